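#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the standard convention).
#' A constant vector has no rank ordering and raises an error rather than
#' returning NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y, method = "spearman")
}

NEFF_BIN_BREAKS <- c(-Inf, 10, 100, 1000, 10000, Inf)
NEFF_BIN_LABELS <- c("D<10", "D10", "D100", "D1000", "D10000")

#' Assign proteins to Neff depth bins
#'
#' Bins follow the evaluation protocol: D10 = [10, 100), D100 = [100, 1000),
#' D1000 = [1000, 10000), D10000 = [10000, Inf); anything below 10 falls in
#' "D<10". So Neff = 30.3 lands in D10.
#'
#' @param neff numeric vector of effective sequence numbers.
#' @return factor of bin labels.
#' @export
neff_bin <- function(neff) {
  cut(neff, breaks = NEFF_BIN_BREAKS, labels = NEFF_BIN_LABELS,
      right = FALSE)
}

#' Evaluate mutation scores against experimental ddG
#'
#' The standard benchmark protocol: for every protein and method, the Spearman rho
#' between the scores and the measured ddG values on their matched mutations
#' (join on position, wt, mt); then the unweighted mean of the per-protein
#' rhos, overall, within Neff depth bins, and — when per-residue RSA is
#' supplied — separately for core (RSA < 20%) and surface (RSA >= 20%)
#' mutations. Since all score tables are oriented "positive = destabilizing",
#' informative methods show positive rho. Proteins with fewer than 3 matched
#' mutations (per stratum) are excluded with a message.
#'
#' @param scores data.frame with columns `protein`, `method`, `position`,
#'   `wt`, `mt`, `score` (stack score tables with [stack_scores()]).
#' @param ddg data.frame with columns `protein`, `position`, `wt`, `mt`,
#'   `ddg` (kcal/mol, positive = destabilizing).
#' @param neff named numeric vector: per-protein Neff.
#' @param rsa optional data.frame `protein`, `resnum`, `rsa`.
#' @param core_cut core/surface RSA boundary (percent), default 20.
#' @return list of class `evostab_eval`: `per_protein` (protein, method, n,
#'   neff, bin, rho), `summary` (method, stratum, mean_rho, n_proteins).
#' @export
evaluate_scores <- function(scores, ddg, neff, rsa = NULL, core_cut = 20) {
  stopifnot(all(c("protein", "method", "position", "wt", "mt", "score")
                %in% names(scores)),
            all(c("protein", "position", "wt", "mt", "ddg") %in% names(ddg)))
  if (anyDuplicated(ddg[, c("protein", "position", "wt", "mt")]))
    stop("duplicate mutations in the ddG table")
  merged <- merge(scores, ddg, by = c("protein", "position", "wt", "mt"))
  if (!is.null(rsa)) {
    merged <- merge(merged, rsa[, c("protein", "resnum", "rsa")],
                    by.x = c("protein", "position"),
                    by.y = c("protein", "resnum"), all.x = TRUE)
    merged$stratum_rsa <- ifelse(merged$rsa < core_cut, "core", "surface")
  }

  rho_block <- function(d) {
    if (nrow(d) < 3L) return(NA_real_)
    tryCatch(spearman_rho(d$score, d$ddg), error = function(e) NA_real_)
  }
  combos <- unique(merged[, c("protein", "method")])
  per <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    d <- merged[merged$protein == combos$protein[k] &
                merged$method == combos$method[k], ]
    data.frame(protein = combos$protein[k], method = combos$method[k],
               n = nrow(d),
               neff = unname(neff[combos$protein[k]]),
               rho = rho_block(d),
               rho_core = if (is.null(rsa)) NA_real_
                          else rho_block(d[!is.na(d$stratum_rsa) &
                                           d$stratum_rsa == "core", ]),
               rho_surface = if (is.null(rsa)) NA_real_
                             else rho_block(d[!is.na(d$stratum_rsa) &
                                              d$stratum_rsa == "surface", ]),
               stringsAsFactors = FALSE)
  }))
  per$bin <- neff_bin(per$neff)
  dropped <- sum(is.na(per$rho))
  if (dropped > 0)
    message(dropped, " protein/method combinations excluded (fewer than 3 ",
            "matched mutations or degenerate ranks)")
  per <- per[order(per$method, per$protein), ]
  rownames(per) <- NULL

  mean_rows <- function(d, col, stratum) {
    ok <- !is.na(d[[col]])
    if (!any(ok)) return(NULL)
    stats::aggregate(d[[col]][ok], by = list(method = d$method[ok]),
                     FUN = mean) |>
      (\(a) data.frame(method = a$method, stratum = stratum,
                       mean_rho = a$x,
                       n_proteins = as.vector(table(d$method[ok])[a$method])))()
  }
  summ <- mean_rows(per, "rho", "all")
  for (b in levels(per$bin)) {
    d <- per[!is.na(per$bin) & per$bin == b, ]
    if (nrow(d)) summ <- rbind(summ, mean_rows(d, "rho", b))
  }
  if (!is.null(rsa)) {
    summ <- rbind(summ, mean_rows(per, "rho_core", "core"),
                  mean_rows(per, "rho_surface", "surface"))
  }
  rownames(summ) <- NULL
  structure(list(per_protein = per, summary = summ),
            class = "evostab_eval")
}

#' @export
print.evostab_eval <- function(x, ...) {
  cat("evostab evaluation:", length(unique(x$per_protein$protein)),
      "proteins,", length(unique(x$per_protein$method)), "methods\n")
  print(x$summary[x$summary$stratum == "all", ], row.names = FALSE)
  invisible(x)
}

#' Stack score tables into the long evaluation format
#'
#' @param tables named list of [new_score_table()]s; names = protein ids. A
#'   nested list (protein -> list of tables) stacks every method per protein.
#' @return data.frame `protein`, `method`, `position`, `wt`, `mt`, `score`.
#' @export
stack_scores <- function(tables) {
  one <- function(protein, tab) {
    data.frame(protein = protein, method = attr(tab, "method"),
               position = tab$position, wt = tab$wt, mt = tab$mt,
               score = tab$score, stringsAsFactors = FALSE)
  }
  out <- lapply(names(tables), function(p) {
    x <- tables[[p]]
    if (inherits(x, "evostab_scores")) one(p, x)
    else do.call(rbind, lapply(x, one, protein = p))
  })
  do.call(rbind, out)
}

#' Uniform subsample of an alignment
#'
#' Keeps the query plus `n - 1` non-query rows sampled uniformly without
#' replacement; reproducible by seed. Used for MSA-depth sensitivity scans.
#'
#' @param aln alignment.
#' @param n total number of sequences to keep (`1 <= n <= N_tot`).
#' @param seed integer seed.
#' @return subsampled alignment (query is row 1).
#' @export
subsample_msa <- function(aln, n, seed) {
  N <- n_seq(aln)
  if (n < 1L || n > N) stop("n out of range [1, ", N, "]")
  others <- setdiff(seq_len(N), aln$query_index)
  keep <- withr::with_seed(seed, others[sample.int(length(others), n - 1L)])
  rows <- c(aln$query_index, sort(keep))
  out <- aln
  out$matrix <- aln$matrix[rows, , drop = FALSE]
  out$ids <- aln$ids[rows]
  out$query_index <- 1L
  out
}
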