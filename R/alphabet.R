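#' @useDynLib evostab, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' The 21-state alignment alphabet
#'
#' All alignment matrices in the package are over 20 standard amino acids plus
#' the gap symbol `"-"`, in this fixed order. The gap is an ordinary 21st
#' state for frequency normalization, sequence identity and Potts inference;
#' it is never a mutant state.
#'
#' @format Character vector of length 21.
#' @export
AA_ALPHABET21 <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Amino-acid states (no gap)
#' @format Character vector of length 20.
#' @export
AA20 <- AA_ALPHABET21[1:20]

# symbols silently remapped to gap by default (ambiguity/nonstandard codes)
NONSTANDARD_AA <- c("B", "Z", "X", "U", "O", "J", "*")

#' Encode alignment symbols as integer states
#'
#' @param m character matrix over [AA_ALPHABET21].
#' @return integer matrix with values in 1..21 (21 = gap).
#' @keywords internal
encode_symbols <- function(m) {
  idx <- match(m, AA_ALPHABET21)
  if (anyNA(idx)) {
    bad <- unique(m[is.na(idx)])
    stop("symbols outside the 21-state alphabet: ",
         paste(shQuote(bad), collapse = ", "))
  }
  matrix(as.integer(idx), nrow = nrow(m), dimnames = dimnames(m))
}

decode_states <- function(x) {
  out <- AA_ALPHABET21[x]
  if (is.matrix(x)) out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  out
}
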