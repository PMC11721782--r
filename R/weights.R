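#' Pairwise sequence identity
#'
#' Fraction of alignment columns carrying identical symbols. Following the
#' plmc convention, the denominator is the full alignment length and the gap
#' is an ordinary 21st symbol, so a gap aligned to a gap counts as a match;
#' `exclude_double_gaps = TRUE` switches to a denominator that skips columns
#' gapped in both sequences (sensitivity checks only).
#'
#' @param s1,s2 symbol vectors of equal length.
#' @param exclude_double_gaps drop columns gapped in both sequences from the
#'   denominator.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(s1, s2, exclude_double_gaps = FALSE) {
  if (length(s1) != length(s2)) stop("sequence length mismatch")
  if (exclude_double_gaps) {
    use <- !(s1 == "-" & s2 == "-")
    if (!any(use)) return(1)
    mean(s1[use] == s2[use])
  } else {
    mean(s1 == s2)
  }
}

#' Sequence weights and the effective number of sequences
#'
#' Each sequence j receives weight w_j = 1/m_j, where m_j is the number of
#' sequences in the alignment (including j itself) with identity >= the
#' threshold (default 80%). Neff = sum_j w_j is the effective number of
#' independent sequences: exact duplicates share their unit of weight, and
#' isolated sequences keep weight one.
#'
#' @param aln alignment.
#' @param identity_threshold similarity level at which sequences share
#'   weight; comparison is `>=` ("at least 80% identity").
#' @param exclude_double_gaps see [pairwise_identity()].
#' @return object of class `evostab_weights`: list with `w` (per-sequence
#'   weights in (0, 1]), `Neff`, `identity_threshold`.
#' @export
compute_weights <- function(aln, identity_threshold = 0.80,
                            exclude_double_gaps = FALSE) {
  if (n_seq(aln) < 1L) stop("empty alignment")
  X <- encode_symbols(aln$matrix)
  m <- neighbor_counts_cpp(X, identity_threshold, exclude_double_gaps)
  w <- 1 / m
  structure(list(w = w, Neff = sum(w),
                 identity_threshold = identity_threshold),
            class = "evostab_weights")
}

#' @export
print.evostab_weights <- function(x, ...) {
  cat(sprintf("evostab weights: %d sequences, Neff = %.3f (threshold %.0f%%)\n",
              length(x$w), x$Neff, 100 * x$identity_threshold))
  invisible(x)
}

#' Uniform (unit) weights for an alignment
#' @param aln alignment.
#' @return `evostab_weights` with all weights one and Neff = N_tot.
#' @export
uniform_weights <- function(aln) {
  structure(list(w = rep(1, n_seq(aln)), Neff = n_seq(aln),
                 identity_threshold = NA_real_),
            class = "evostab_weights")
}
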