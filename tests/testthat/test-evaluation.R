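test_that("Spearman rho handles perfect, reversed and tied rankings", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # tie handled by average ranks; frozen value from direct rank arithmetic:
  # ranks y = (1, 2.5, 2.5, 4), cov = 4.5, sds = sqrt(5), sqrt(4.5)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 2, 2, 4)),
               4.5 / sqrt(5 * 4.5), tolerance = 1e-12)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  # invariance under strictly monotone transforms
  set.seed(61)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(spearman_rho(exp(a), b^3 + 2 * b), spearman_rho(a, b))
})

test_that("Neff bins follow the D10/D100/D1000/D10000 boundaries", {
  expect_equal(as.character(neff_bin(c(30.3, 9.99, 10, 99.9, 100, 5000, 1e5))),
               c("D10", "D<10", "D10", "D10", "D100", "D1000", "D10000"))
})

test_that("evaluation reports per-protein rho and unweighted means", {
  ddg <- data.frame(protein = rep(c("p1", "p2"), each = 5),
                    position = rep(1:5, 2), wt = "A",
                    mt = rep(c("C", "D", "E", "F", "G"), 2),
                    ddg = c(1, 2, 3, 4, 5, 2, 1, 4, 3, 5))
  perfect <- data.frame(protein = "p1", method = "m", position = 1:5,
                        wt = "A", mt = c("C", "D", "E", "F", "G"),
                        score = c(1, 2, 3, 4, 5))
  ev1 <- evaluate_scores(perfect, ddg[ddg$protein == "p1", ],
                         neff = c(p1 = 30.3))
  expect_equal(ev1$per_protein$rho, 1)
  expect_equal(as.character(ev1$per_protein$bin), "D10")
  expect_equal(ev1$summary$mean_rho[ev1$summary$stratum == "all"], 1)

  # unweighted mean over proteins: rho 0.2 & 0.6 -> 0.4 regardless of counts
  s1 <- data.frame(protein = "p1", method = "m", position = 1:5, wt = "A",
                   mt = c("C", "D", "E", "F", "G"), score = c(1, 2, 3, 5, 4))
  s2 <- data.frame(protein = "p2", method = "m", position = 1:5, wt = "A",
                   mt = c("C", "D", "E", "F", "G"), score = c(2, 1, 4, 3, 5))
  rho1 <- spearman_rho(s1$score, ddg$ddg[ddg$protein == "p1"])
  rho2 <- spearman_rho(s2$score, ddg$ddg[ddg$protein == "p2"])
  ev <- evaluate_scores(rbind(s1, s2), ddg, neff = c(p1 = 50, p2 = 2000))
  expect_equal(ev$summary$mean_rho[ev$summary$stratum == "all"],
               mean(c(rho1, rho2)))

  # the bin-weighted mean of bin means equals the overall mean
  summ <- ev$summary
  bins <- summ[!summ$stratum %in% c("all", "core", "surface"), ]
  expect_equal(sum(bins$mean_rho * bins$n_proteins) / sum(bins$n_proteins),
               summ$mean_rho[summ$stratum == "all"])
})

test_that("evaluation is invariant to row order and drops tiny overlaps", {
  set.seed(62)
  ddg <- data.frame(protein = "p1", position = rep(1:10, each = 2), wt = "A",
                    mt = rep(c("C", "D"), 10), ddg = rnorm(20))
  sc <- data.frame(protein = "p1", method = "m", position = ddg$position,
                   wt = "A", mt = ddg$mt, score = rnorm(20))
  ev_a <- evaluate_scores(sc, ddg, neff = c(p1 = 500))
  shuffle <- sample(nrow(sc))
  ev_b <- evaluate_scores(sc[shuffle, ], ddg[sample(nrow(ddg)), ],
                          neff = c(p1 = 500))
  expect_equal(ev_a$per_protein$rho, ev_b$per_protein$rho)

  tiny <- sc[1:2, ]
  tiny$protein <- "p2"
  ddg2 <- ddg[1:2, ]; ddg2$protein <- "p2"
  expect_message(
    ev <- evaluate_scores(rbind(sc, tiny), rbind(ddg, ddg2),
                          neff = c(p1 = 500, p2 = 500)),
    "excluded")
  expect_true(is.na(ev$per_protein$rho[ev$per_protein$protein == "p2"]))
  expect_error(evaluate_scores(sc, rbind(ddg, ddg[1, ]), neff = c(p1 = 1)),
               "duplicate")
})

test_that("core/surface strata split per-mutation at RSA 20%", {
  set.seed(63)
  # core positions 1-5 carry signal; surface positions 6-10 carry noise
  ddg <- data.frame(protein = "p1", position = rep(1:10, each = 3), wt = "A",
                    mt = rep(c("C", "D", "E"), 10), ddg = NA_real_)
  sc <- ddg; sc$method <- "m"; sc$score <- rnorm(30)
  sc$ddg <- NULL
  ddg$ddg <- ifelse(ddg$position <= 5, sc$score, rnorm(30))
  rsa <- data.frame(protein = "p1", resnum = 1:10,
                    rsa = c(rep(5, 5), rep(60, 5)))
  ev <- evaluate_scores(sc, ddg, neff = c(p1 = 100), rsa = rsa)
  expect_equal(ev$per_protein$rho_core, 1)
  expect_lt(ev$per_protein$rho_surface, 1)
  expect_equal(ev$summary$mean_rho[ev$summary$stratum == "core"], 1)
})

test_that("MSA subsampling retains the query and is seed-reproducible", {
  set.seed(64)
  aln <- random_alignment(20, 12)
  sub <- subsample_msa(aln, 8, seed = 7)
  expect_equal(n_seq(sub), 8L)
  expect_equal(sub$matrix[1, ], aln$matrix[1, ])
  expect_identical(subsample_msa(aln, 8, seed = 7)$ids, sub$ids)
  expect_false(identical(subsample_msa(aln, 8, seed = 8)$ids, sub$ids))
  full <- subsample_msa(aln, 20, seed = 1)
  expect_setequal(full$ids, aln$ids)
  expect_error(subsample_msa(aln, 0, seed = 1), "range")
  expect_error(subsample_msa(aln, 21, seed = 1), "range")

  # subsampling cannot raise Neff above the full alignment's
  red <- inject_redundancy(random_alignment(10, 30), copies = 3,
                           mutation_rate = 0.03, seed = 9)
  neff_full <- compute_weights(red)$Neff
  neff_sub <- mean(vapply(1:10, function(s)
    compute_weights(subsample_msa(red, n_seq(red) %/% 2, seed = s))$Neff,
    numeric(1)))
  expect_lte(neff_sub, neff_full)
})
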