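#' Regularized positional frequency model
#'
#' Computes per-column amino-acid frequencies over the 21 states (20 amino
#' acids + gap) at every query-resolved column, plus the background frequency
#' over all columns of the full alignment, and regularizes both as
#' `f_reg = f * (1 - theta) + theta / 21`. With a weight vector the raw counts
#' are weight-rectified first (`f_i^w(a) = sum_j w_j d(a, a_ij) / sum_j w_j`)
#' and the same regularization is then applied to the weighted frequencies.
#'
#' @param aln alignment.
#' @param weights optional [compute_weights()] result; `NULL` = unweighted.
#' @param theta regularization factor in `[0, 1)`; default 0.01.
#' @param background_all_columns background over all columns of the full MSA
#'   (default) or only the query-resolved ones.
#' @return object of class `evostab_freqs`: `f_site` (L_q x 21 regularized),
#'   `f_site_raw`, `f_bg` (length 21, regularized), `f_bg_raw`, `theta`,
#'   `weighted`, `positions` (1-based query positions of the rows),
#'   `query` (query residues at those positions).
#' @export
build_frequency_model <- function(aln, weights = NULL, theta = 0.01,
                                  background_all_columns = TRUE) {
  stopifnot(theta >= 0, theta < 1)
  if (n_seq(aln) < 1L) stop("empty alignment")
  w <- if (is.null(weights)) rep(1, n_seq(aln)) else weights$w
  stopifnot(length(w) == n_seq(aln))
  X <- encode_symbols(aln$matrix)
  wsum <- sum(w)

  count_col <- function(col) {
    cnt <- numeric(21L)
    for (s in seq_along(col)) cnt[col[s]] <- cnt[col[s]] + w[s]
    cnt
  }
  resolved <- which(!is.na(aln$column_map))
  f_raw <- t(vapply(resolved, function(j) count_col(X[, j]) / wsum,
                    numeric(21L)))
  colnames(f_raw) <- AA_ALPHABET21

  bg_cols <- if (background_all_columns) seq_len(ncol(X)) else resolved
  bg_cnt <- numeric(21L)
  for (j in bg_cols) bg_cnt <- bg_cnt + count_col(X[, j])
  f_bg_raw <- bg_cnt / sum(bg_cnt)
  names(f_bg_raw) <- AA_ALPHABET21

  reg <- function(f) f * (1 - theta) + theta / 21
  structure(list(
    f_site = reg(f_raw), f_site_raw = f_raw,
    f_bg = reg(f_bg_raw), f_bg_raw = f_bg_raw,
    theta = theta, weighted = !is.null(weights),
    positions = aln$column_map[resolved],
    query = aln$matrix[aln$query_index, resolved]
  ), class = "evostab_freqs")
}

#' @export
print.evostab_freqs <- function(x, ...) {
  cat(sprintf("evostab frequency model: %d positions, theta = %g, %s\n",
              nrow(x$f_site), x$theta,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

freq_row <- function(freqs, i) {
  r <- match(i, freqs$positions)
  if (is.na(r)) stop("position ", i, " is not query-resolved")
  freqs$f_site[r, ]
}

#' Conservation index
#'
#' Root of half the summed squared deviations of a column's regularized
#' amino-acid frequencies from the alignment background, over the 20 amino
#' acids (the gap participates in normalization but not in the sum). 0 for a
#' column indistinguishable from the background; bounded below 1 for
#' `theta > 0`.
#'
#' @param freqs [build_frequency_model()] result.
#' @param i 1-based query position.
#' @return nonnegative scalar.
#' @export
conservation_index <- function(freqs, i) {
  f <- freq_row(freqs, i)
  d <- f[AA20] - freqs$f_bg[AA20]
  sqrt(0.5 * sum(d^2))
}

logit <- function(x) log(x / (1 - x))

#' Log-odds ratio of wild-type vs mutant residue
#'
#' `LOR(i, wt, mt) = logit(f_i(wt)) - logit(f_i(mt))` on the regularized
#' positional frequencies, natural log. A frequent wild type mutated to a
#' rare residue scores positive, comparable to a destabilizing mutation.
#' On a weighted frequency model this is the weighted score LORw.
#'
#' @param freqs frequency model.
#' @param i 1-based query position.
#' @param wt wild-type residue; must equal the query residue at `i`.
#' @param mt mutant residue (one of the 20 amino acids, not a gap).
#' @return scalar log-odds difference.
#' @export
lor <- function(freqs, i, wt, mt) {
  if (!mt %in% AA20) stop("mutant state must be one of the 20 amino acids")
  if (!wt %in% AA20) stop("wild-type state must be one of the 20 amino acids")
  f <- freq_row(freqs, i)
  qres <- freqs$query[match(i, freqs$positions)]
  if (wt != qres)
    stop(sprintf("wt %s does not match query residue %s at position %d",
                 wt, qres, i))
  fw <- unname(f[wt]); fm <- unname(f[mt])
  if (fw >= 1 || fm >= 1)
    stop("frequency of 1 gives an infinite logit; use theta > 0 regularization")
  logit(fw) - logit(fm)
}

#' @rdname lor
#' @export
lorw <- function(freqs, i, wt, mt) {
  if (!isTRUE(freqs$weighted))
    stop("lorw requires a frequency model built with sequence weights")
  lor(freqs, i, wt, mt)
}

# ---- score tables ------------------------------------------------------

#' Mutation score table
#'
#' A `data.frame` with columns `position` (1-based query position), `wt`,
#' `mt`, `score`, carrying attributes `method` and `orientation`
#' (always "positive = predicted destabilizing").
#'
#' @param df data.frame with the four columns above.
#' @param method method label.
#' @return the data.frame with class `evostab_scores` prepended.
#' @export
new_score_table <- function(df, method) {
  stopifnot(all(c("position", "wt", "mt", "score") %in% names(df)))
  if (anyDuplicated(df[, c("position", "mt")]))
    stop("duplicate (position, mt) rows in score table")
  structure(df, method = method,
            orientation = "positive = predicted destabilizing",
            class = c("evostab_scores", "data.frame"))
}

#' Independent-site score table over all single substitutions
#'
#' Emits LOR/LORw scores for the 19 non-wild-type amino acids at every
#' query-resolved position, or the per-position conservation index (one row
#' per position, `mt = NA`).
#'
#' @param freqs frequency model.
#' @param method `"lor"`, `"lorw"` or `"ci"`.
#' @return an [new_score_table()].
#' @export
site_score_table <- function(freqs, method = c("lor", "lorw", "ci")) {
  method <- match.arg(method)
  if (method == "lorw" && !isTRUE(freqs$weighted))
    stop("lorw requires a weighted frequency model")
  pos <- freqs$positions
  if (method == "ci") {
    df <- data.frame(position = pos, wt = freqs$query, mt = NA_character_,
                     score = vapply(pos, conservation_index,
                                    numeric(1), freqs = freqs))
    return(new_score_table(df, method))
  }
  rows <- lapply(seq_along(pos), function(r) {
    wt <- freqs$query[r]
    mts <- setdiff(AA20, wt)
    f <- freqs$f_site[r, ]
    data.frame(position = pos[r], wt = wt, mt = mts,
               score = unname(logit(f[wt]) - logit(f[mts])))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  new_score_table(df, method)
}

#' Write / read mutation score tables as TSV
#' @param scores score table.
#' @param path file path.
#' @return `path` invisibly (write) or a score table (read).
#' @export
write_score_table <- function(scores, path) {
  hdr <- sprintf("# method=%s orientation=%s",
                 attr(scores, "method"), attr(scores, "orientation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
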