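# shared fixtures and independent oracles, all built in code

aln_from_strings <- function(seqs, ids = names(seqs), query_index = 1L) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  new_alignment(m, ids = ids, query_index = query_index)
}

write_fasta_tmp <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# random gapped alignment over the full 21-state alphabet
random_alignment <- function(N, L, gap_prob = 0.1) {
  syms <- sample(AA_ALPHABET21[1:20], N * L, replace = TRUE)
  gaps <- runif(N * L) < gap_prob
  syms[gaps] <- "-"
  m <- matrix(syms, N, L)
  m[1, ] <- sample(AA_ALPHABET21[1:20], L, replace = TRUE)  # ungapped query
  new_alignment(m)
}

# O(N^2 L) brute-force double-loop weight oracle (independent of the
# compiled implementation)
brute_force_weights <- function(aln, threshold = 0.80) {
  m <- aln$matrix
  N <- nrow(m)
  w <- numeric(N)
  for (j in seq_len(N)) {
    mj <- 0L
    for (k in seq_len(N)) {
      match_count <- 0L
      for (col in seq_len(ncol(m)))
        if (m[j, col] == m[k, col]) match_count <- match_count + 1L
      if (match_count / ncol(m) >= threshold) mj <- mj + 1L
    }
    w[j] <- 1 / mj
  }
  w
}

# exhaustive Boltzmann enumeration for tiny Potts models (explicit Z)
enum_boltzmann <- function(model) {
  L <- model$L; q <- model$q
  states <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  en <- apply(states, 1, function(s) {
    e <- sum(model$h[cbind(seq_len(L), s)])
    for (i in seq_len(L - 1)) for (j in (i + 1):L)
      e <- e + model$J[s[i], s[j], pair_index(i, j, L)]
    e
  })
  z <- sum(exp(en - max(en)))
  list(states = states, p = exp(en - max(en)) / z)
}

random_potts <- function(L, q, sd_h = 0.5, sd_J = 0.3, lambda_h = NA,
                         lambda_J = NA) {
  new_potts(matrix(rnorm(L * q, sd = sd_h), L, q),
            array(rnorm(q * q * L * (L - 1) / 2, sd = sd_J),
                  dim = c(q, q, L * (L - 1) / 2)),
            q = q, lambda_h = lambda_h, lambda_J = lambda_J)
}

encode_aln <- function(aln) {
  x <- match(aln$matrix, AA_ALPHABET21)
  dim(x) <- dim(aln$matrix)
  x
}
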