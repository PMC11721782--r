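#' Alignment container
#'
#' An `evostab_alignment` is a plain list with a character symbol matrix over
#' the 21-state alphabet (rows = sequences, columns = alignment columns), the
#' sequence ids, the row index of the query sequence, and `column_map`: for
#' every retained column, the 1-based position in the ungapped query sequence
#' (`NA` for columns where the query carries a gap). Alignment columns are
#' indexed 0-free (ordinary R 1-based matrix columns); query positions are
#' 1-based everywhere, matching the usual "V54S" mutation notation.
#'
#' @param matrix character matrix of symbols in [AA_ALPHABET21].
#' @param ids character vector of sequence identifiers (length `nrow(matrix)`).
#' @param query_index row index of the query sequence (default 1).
#' @return An object of class `evostab_alignment`.
#' @export
new_alignment <- function(matrix, ids = rownames(matrix), query_index = 1L) {
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("`matrix` must be a character matrix")
  if (nrow(matrix) < 1L) stop("empty alignment: no sequences")
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(matrix)))
  if (length(ids) != nrow(matrix)) stop("length(ids) != nrow(matrix)")
  encode_symbols(matrix)  # validates the alphabet
  query_index <- as.integer(query_index)
  if (query_index < 1L || query_index > nrow(matrix))
    stop("query_index out of range")
  aln <- structure(
    list(ids = as.character(ids), matrix = unname(matrix),
         query_index = query_index,
         column_map = query_column_map(matrix[query_index, ])),
    class = "evostab_alignment")
  aln
}

query_column_map <- function(query_row) {
  resolved <- query_row != "-"
  cm <- rep(NA_integer_, length(query_row))
  cm[resolved] <- seq_len(sum(resolved))
  cm
}

#' @export
print.evostab_alignment <- function(x, ...) {
  cat(sprintf("evostab alignment: %d sequences x %d columns (%d query-resolved)\n",
              nrow(x$matrix), ncol(x$matrix), sum(!is.na(x$column_map))))
  cat(sprintf("query: %s (row %d)\n", x$ids[x$query_index], x$query_index))
  invisible(x)
}

#' Number of sequences / alignment columns
#' @param aln an [new_alignment()] object.
#' @export
n_seq <- function(aln) nrow(aln$matrix)

#' @rdname n_seq
#' @export
n_col <- function(aln) ncol(aln$matrix)

#' Query sequence (ungapped) of an alignment
#' @param aln alignment.
#' @return character vector of residues at query-resolved columns.
#' @export
query_sequence <- function(aln) {
  aln$matrix[aln$query_index, !is.na(aln$column_map)]
}

# ---- reading -----------------------------------------------------------

#' Read a multiple sequence alignment
#'
#' Reads FASTA, A2M or Stockholm alignments into the package's 21-state
#' representation. Symbols are uppercased and `.` is read as a gap.
#' In A2M files lowercase letters mark insert states: by default every column
#' containing an insert state is dropped (the usual treatment of
#' jackhmmer-style output); with `keep_inserts = TRUE` insert columns are
#' kept, uppercased, and flagged in `attr(, "insert_columns")`.
#' Nonstandard letters (B, Z, X, U, O, J and `*`) are remapped via
#' `nonstandard_to` (gap by default) so that 21-state frequency
#' normalization stays exact; any other symbol is an error naming it.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"a2m"`, `"stockholm"`. Default guesses
#'   from the extension (`.sto`/`.stk` = Stockholm, otherwise FASTA/A2M,
#'   which share a reader).
#' @param query_id optional id of the query sequence; default: first record.
#' @param keep_inserts keep (uppercase) A2M insert columns instead of
#'   dropping them.
#' @param nonstandard_to single symbol nonstandard letters map to.
#' @return an [new_alignment()] object.
#' @export
read_alignment <- function(path, format = NULL, query_id = NULL,
                           keep_inserts = FALSE, nonstandard_to = "-") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  }
  format <- match.arg(format, c("fasta", "a2m", "stockholm"))
  recs <- if (format == "stockholm") read_stockholm_records(path)
          else read_fasta_records(path)
  if (length(recs$seq) == 0L) stop("empty alignment file: ", path)
  lens <- nchar(recs$seq)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  m <- do.call(rbind, strsplit(recs$seq, ""))

  # A2M conventions: '.' is a gap, lowercase letters are insert states
  is_lower <- m %in% letters
  dim(is_lower) <- dim(m)
  insert_cols <- which(apply(is_lower | m == ".", 2, any))
  m[m == "."] <- "-"
  m <- toupper(m)          # drops dim attributes
  dim(m) <- dim(is_lower)
  if (length(insert_cols) && !keep_inserts) {
    m <- m[, -insert_cols, drop = FALSE]
    insert_cols <- integer(0)
  }
  ns <- m %in% NONSTANDARD_AA
  if (any(ns)) m[ns] <- nonstandard_to

  qi <- 1L
  if (!is.null(query_id)) {
    qi <- match(query_id, recs$id)
    if (is.na(qi)) stop("query id not found: ", query_id)
  }
  aln <- new_alignment(m, ids = recs$id, query_index = qi)
  attr(aln, "insert_columns") <- insert_cols
  aln
}

read_fasta_records <- function(path) {
  x <- Biostrings::readBStringSet(path)
  list(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

# Minimal Stockholm reader: '# ' annotation lines skipped, '//' terminates,
# wrapped blocks concatenated by sequence name.
read_stockholm_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order_ids <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "//")) break
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed Stockholm line: ", ln)
    id <- parts[1]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- parts[2]
      order_ids <- c(order_ids, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], parts[2])
    }
  }
  list(id = order_ids, seq = unlist(seqs[order_ids], use.names = FALSE))
}

#' Write an alignment as FASTA
#'
#' @param aln alignment.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$matrix, 1, paste0, collapse = "")
  writeLines(paste0(">", aln$ids, "\n", seqs), path)
  invisible(path)
}

# ---- curation ----------------------------------------------------------

#' Remove alignment columns with a high gap fraction
#'
#' Drops columns whose gap fraction exceeds `max_gap_freq` (the usual
#' trimming threshold is 0.2: a column with gaps in strictly more than 20%
#' of the sequences is removed). With `protect_query = TRUE` (default),
#' query-resolved columns are always kept so that every query position
#' remains scoreable.
#'
#' @param aln alignment.
#' @param max_gap_freq maximal tolerated gap fraction in `[0, 1]`.
#' @param protect_query never drop columns where the query has a residue.
#' @return trimmed alignment; `column_map` keeps the original query positions.
#' @export
trim_gapped_columns <- function(aln, max_gap_freq = 0.2, protect_query = TRUE) {
  stopifnot(max_gap_freq >= 0, max_gap_freq <= 1)
  gap_frac <- colMeans(aln$matrix == "-")
  keep <- gap_frac <= max_gap_freq
  if (protect_query) keep <- keep | !is.na(aln$column_map)
  if (!any(keep)) stop("trimming removed every column")
  subset_columns(aln, which(keep))
}

subset_columns <- function(aln, cols) {
  out <- aln
  out$matrix <- aln$matrix[, cols, drop = FALSE]
  out$column_map <- aln$column_map[cols]
  out
}

#' Filter sequences on gap ratio and identity to the query
#'
#' Keeps the query plus every sequence passing all active filters; a filter
#' left `NULL` is skipped. Identity to the query uses [pairwise_identity()]
#' (full alignment length, gap as a 21st symbol).
#'
#' @param aln alignment.
#' @param max_gap_ratio drop sequences whose gap fraction exceeds this.
#' @param min_query_id,max_query_id bounds (inclusive) on identity with the
#'   query.
#' @return filtered alignment (query row always retained).
#' @export
filter_sequences <- function(aln, max_gap_ratio = NULL,
                             min_query_id = NULL, max_query_id = NULL) {
  for (v in c(max_gap_ratio, min_query_id, max_query_id))
    stopifnot(v >= 0, v <= 1)
  keep <- rep(TRUE, n_seq(aln))
  if (!is.null(max_gap_ratio))
    keep <- keep & rowMeans(aln$matrix == "-") <= max_gap_ratio
  if (!is.null(min_query_id) || !is.null(max_query_id)) {
    q <- aln$matrix[aln$query_index, ]
    ident <- rowMeans(sweep(aln$matrix, 2, q, "=="))
    if (!is.null(min_query_id)) keep <- keep & ident >= min_query_id
    if (!is.null(max_query_id)) keep <- keep & ident <= max_query_id
  }
  keep[aln$query_index] <- TRUE
  out <- aln
  out$matrix <- aln$matrix[keep, , drop = FALSE]
  out$ids <- aln$ids[keep]
  out$query_index <- match(aln$query_index, which(keep))
  out
}

#' Restrict an alignment to its query-resolved columns
#'
#' Used before Potts inference and positional scoring so that model position
#' i corresponds to query position `column_map[i]`.
#'
#' @param aln alignment.
#' @return alignment containing only columns where the query has a residue.
#' @export
query_resolved <- function(aln) {
  subset_columns(aln, which(!is.na(aln$column_map)))
}
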