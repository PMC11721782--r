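test_that("pseudo-log-likelihood at zero parameters equals -Neff * L * log(q)", {
  set.seed(41)
  q <- 4; L <- 6
  aln <- sample_msa(make_planted_model(L, q, seed = 1), 40, seed = 2)
  w <- compute_weights(aln)
  mod <- new_potts(matrix(0, L, q), array(0, dim = c(q, q, L * (L - 1) / 2)),
                   q = q, lambda_h = 0, lambda_J = 0)
  expect_equal(pseudo_log_likelihood(mod, aln, w)$value,
               -w$Neff * L * log(q))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(42)
  L <- 4; q <- 3
  aln <- sample_msa(make_planted_model(L, q, seed = 3), 25, seed = 4)
  w <- compute_weights(aln)
  mod <- random_potts(L, q, lambda_h = 0.01, lambda_J = 0.02)
  res <- pseudo_log_likelihood(mod, aln, w)
  eps <- 1e-5
  for (k in 1:10) {
    if (k %% 2 == 0) {
      i <- sample(L, 1); a <- sample(q, 1)
      up <- mod; up$h[i, a] <- up$h[i, a] + eps
      dn <- mod; dn$h[i, a] <- dn$h[i, a] - eps
      an <- res$grad_h[i, a]
    } else {
      p <- sample(dim(mod$J)[3], 1); a <- sample(q, 1); b <- sample(q, 1)
      up <- mod; up$J[a, b, p] <- up$J[a, b, p] + eps
      dn <- mod; dn$J[a, b, p] <- dn$J[a, b, p] - eps
      an <- res$grad_J[a, b, p]
    }
    fd <- (pseudo_log_likelihood(up, aln, w)$value -
           pseudo_log_likelihood(dn, aln, w)$value) / (2 * eps)
    expect_lt(abs(an - fd) / max(abs(fd), 1e-8), 1e-5)
  }
  bad <- mod; bad$h[1, 1] <- NaN
  expect_error(pseudo_log_likelihood(bad, aln, w), "non-finite")
})

test_that("conditionals and unpenalized likelihood carry a gauge freedom", {
  set.seed(43)
  L <- 5; q <- 4
  aln <- sample_msa(make_planted_model(L, q, seed = 5), 30, seed = 6)
  w <- compute_weights(aln)
  for (rep in 1:5) {
    mod <- random_potts(L, q)
    gz <- zero_sum_gauge(mod)
    # zero-sum constraints hold
    expect_lt(max(abs(rowSums(gz$h))), 1e-8)
    for (p in seq_len(dim(gz$J)[3])) {
      expect_lt(max(abs(rowSums(gz$J[, , p]))), 1e-8)
      expect_lt(max(abs(colSums(gz$J[, , p]))), 1e-8)
    }
    # probabilities unchanged
    s <- sample(q, L, replace = TRUE)
    expect_equal(site_conditionals(mod, s), site_conditionals(gz, s),
                 tolerance = 1e-8)
    expect_equal(pseudo_log_likelihood(mod, aln, w)$value,
                 pseudo_log_likelihood(gz, aln, w)$value, tolerance = 1e-8)
    # adding a constant to a site's fields changes nothing either
    shifted <- mod
    shifted$h[2, ] <- shifted$h[2, ] + 3.7
    expect_equal(site_conditionals(mod, s), site_conditionals(shifted, s),
                 tolerance = 1e-10)
  }
})

test_that("mutation_score evaluates the field and coupling differences", {
  # hand-built model: h_1(A) = 1.0, h_1(C) = 0.5, J_13(A, W) = 0.2, query AAW
  q <- 21; L <- 3
  h <- matrix(0, L, q); J <- array(0, dim = c(q, q, 3))
  codeA <- match("A", AA_ALPHABET21); codeC <- match("C", AA_ALPHABET21)
  codeW <- match("W", AA_ALPHABET21)
  h[1, codeA] <- 1.0; h[1, codeC] <- 0.5
  J[codeA, codeW, pair_index(1, 3, L)] <- 0.2
  query <- c(codeA, codeA, codeW)
  mod <- new_potts(h, J, q = q, query = query)
  expect_equal(mutation_score(mod, 1, "A", "C"), (0.5 - 1.0) + (0 - 0.2))
  expect_equal(mutation_score(mod, 1, "A", "A"), 0)
  expect_error(mutation_score(mod, 1, "A", "-"), "gap")
  expect_error(mutation_score(mod, 1, "C", "D"), "does not match")

  # all-zero couplings reduce to the field difference
  modf <- new_potts(h, array(0, dim = c(q, q, 3)), q = q, query = query)
  expect_equal(mutation_score(modf, 1, "A", "C"), -0.5)
})

test_that("Frobenius map is the coupling-block norm over amino-acid states", {
  q <- 21; L <- 3
  zero <- new_potts(matrix(0, L, q), array(0, dim = c(q, q, 3)), q = q)
  expect_true(all(frobenius_map(zero)$F == 0))

  J <- array(0, dim = c(q, q, 3))
  J[3, 5, pair_index(1, 2, L)] <- 2        # single entry, gauge bypassed
  m1 <- new_potts(matrix(0, L, q), J, q = q, gauge = "zero-sum")
  f1 <- frobenius_map(m1, assume_zero_sum = TRUE)
  expect_equal(f1$F[1, 2], 2)
  expect_equal(f1$F[2, 1], 2)
  expect_equal(diag(f1$F), rep(0, L))

  J2 <- array(0, dim = c(q, q, 3))
  J2[1, 1, pair_index(2, 3, L)] <- 1
  J2[2, 2, pair_index(2, 3, L)] <- 1
  m2 <- new_potts(matrix(0, L, q), J2, q = q, gauge = "zero-sum")
  expect_equal(frobenius_map(m2, assume_zero_sum = TRUE)$F[2, 3], sqrt(2))

  # gap entries excluded by default, included on request
  J3 <- array(0, dim = c(q, q, 3))
  J3[21, 4, pair_index(1, 2, L)] <- 5
  m3 <- new_potts(matrix(0, L, q), J3, q = q, gauge = "zero-sum")
  expect_equal(frobenius_map(m3, assume_zero_sum = TRUE)$F[1, 2], 0)
  expect_equal(frobenius_map(m3, assume_zero_sum = TRUE,
                             gap_excluded = FALSE)$F[1, 2], 5)
})

test_that("pruning interpolates between full epistatic and fields-only scores", {
  set.seed(44)
  q <- 8; L <- 6
  mod <- zero_sum_gauge(random_potts(L, q))
  fm <- frobenius_map(mod)
  wt_code <- mod$query[2]
  wt <- AA_ALPHABET21[wt_code]
  b <- AA_ALPHABET21[setdiff(seq_len(q), wt_code)[1]]
  full <- mutation_score(mod, 2, wt, b)
  expect_equal(pruned_mutation_score(mod, fm, 0, 2, wt, b), full)
  tmax <- max(fm$F) + 1
  expect_equal(pruned_mutation_score(mod, fm, tmax, 2, wt, b),
               mod$h[2, match(b, AA_ALPHABET21)] - mod$h[2, wt_code])

  # two-pair toy model: at t = 1 only the strong pair contributes
  q2 <- 4; L2 <- 3
  h <- matrix(0, L2, q2); J <- array(0, dim = c(q2, q2, 3))
  J[1, 2, pair_index(1, 2, L2)] <- 0.5   # F_12 = 0.5
  J[2, 3, pair_index(1, 3, L2)] <- 2.0   # F_13 = 2.0
  query <- c(1L, 2L, 3L)
  toy <- new_potts(h, J, q = q2, query = query, gauge = "zero-sum")
  fmt <- frobenius_map(toy, assume_zero_sum = TRUE)
  expect_equal(fmt$F[1, 2], 0.5)
  expect_equal(fmt$F[1, 3], 2.0)
  # hand evaluation of A -> C at position 1 (codes 1 -> 2):
  #   pair (1,2): J(b=2, s2=2) - J(a=1, s2=2) = 0 - 0.5
  #   pair (1,3): J(b=2, s3=3) - J(a=1, s3=3) = 2.0 - 0
  expect_equal(mutation_score(toy, 1, "A", "C"), -0.5 + 2.0)
  expect_equal(pruned_mutation_score(toy, fmt, 1.0, 1, "A", "C"), 2.0)
  expect_equal(pruned_mutation_score(toy, fmt, 2.5, 1, "A", "C"), 0)

  # coverage is nested as t decreases
  ts <- sort(c(0, runif(4, 0, max(fm$F) + 0.5)), decreasing = TRUE)
  sets <- lapply(ts, function(t) which(fm$F[2, ] > t))
  for (k in seq_len(length(sets) - 1))
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
})

test_that("fitted conditionals recover the generating model on a tiny alphabet", {
  m <- make_planted_model(2, 2, data.frame(i = 1, j = 2, strength = 0.8),
                          field_scale = 0.5, seed = 11)
  aln <- sample_msa(m, 4000, seed = 12)
  fit <- fit_potts(aln, uniform_weights(aln), q = 2)
  expect_true(fit$converged)
  for (s2 in 1:2) {
    s <- c(1L, s2)
    expect_equal(site_conditionals(fit, s)[1, ], site_conditionals(m, s)[1, ],
                 tolerance = 0.05)
  }
})

test_that("very strong coupling penalty reduces scores to the fields-only limit", {
  set.seed(45)
  m <- make_planted_model(4, 4, data.frame(i = 1, j = 3, strength = 1),
                          seed = 13)
  aln <- sample_msa(m, 300, seed = 14)
  w <- uniform_weights(aln)
  fit <- fit_potts(aln, w, lambda_h = 0.01, lambda_J = 1e6, q = 4)
  expect_lt(max(abs(fit$J)), 1e-3)
  fm <- frobenius_map(fit)
  wt_code <- fit$query[1]; wt <- AA_ALPHABET21[wt_code]
  b <- AA_ALPHABET21[setdiff(1:4, wt_code)[1]]
  zs <- zero_sum_gauge(fit)
  expect_equal(mutation_score(zs, 1, wt, b),
               zs$h[1, match(b, AA_ALPHABET21)] - zs$h[1, wt_code],
               tolerance = 1e-3)
})

test_that("potts score tables emit the destabilizing-positive orientation", {
  set.seed(46)
  m <- make_planted_model(5, 6, NULL, field_scale = 1.2, seed = 15)
  aln <- sample_msa(m, 500, seed = 16)
  fit <- fit_potts(aln, uniform_weights(aln), q = 6)
  tab <- potts_score_table(fit)
  expect_equal(attr(tab, "orientation_sign"), -1)
  expect_equal(nrow(tab), 5 * 5)
  k <- sample(nrow(tab), 8)
  expect_equal(tab$score[k],
               -mapply(function(p, a, b) mutation_score(fit, p, a, b),
                       tab$position[k], tab$wt[k], tab$mt[k]))
  # common wild types have larger fitted fields, so mutating away from them
  # scores positive on average
  expect_gt(mean(tab$score), 0)
})
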