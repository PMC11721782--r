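test_that("isolated-atom SASA matches the closed-form sphere area", {
  at <- data.frame(element = "C", x = 0, y = 0, z = 0, radius = 1.7,
                   chain = "A", resnum = 1L, aa = "A")
  s <- compute_sasa(at)
  expect_equal(s$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("an atom caged by tight neighbors is fully buried", {
  shell <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  shell <- shell[!(shell$x == 0 & shell$y == 0 & shell$z == 0), ]
  at <- rbind(data.frame(element = "C", x = 0, y = 0, z = 0, radius = 1.7,
                         chain = "A", resnum = 1L, aa = "A"),
              data.frame(element = "C", x = shell$x, y = shell$y, z = shell$z,
                         radius = 1.7, chain = "A", resnum = 2L, aa = "A"))
  s <- compute_sasa(at)
  expect_equal(s$sasa[s$resnum == 1L], 0)
})

test_that("SASA converges in the surface point count", {
  p <- make_toy_structure("gxg_extended", "V")
  at <- parse_structure(p)
  s1 <- compute_sasa(at, n_points = 960L)
  s2 <- compute_sasa(at, n_points = 1920L)
  expect_true(all(abs(s2$sasa - s1$sasa) / pmax(s1$sasa, 1) < 0.005))
  expect_error(compute_sasa(at, n_points = 50L))
})

test_that("SASA is invariant under rigid rotation and translation", {
  p <- make_toy_structure("helix", "L", n_res = 8)
  at <- parse_structure(p)
  # the surface lattice is fixed in space, so rotation invariance holds up to
  # the sampling resolution; a dense, converged lattice brings it below 0.1%
  s0 <- compute_sasa(at, n_points = 30000L)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R
  at2 <- at
  at2$x <- xyz[, 1] + 11.3; at2$y <- xyz[, 2] - 4.2; at2$z <- xyz[, 3] + 0.7
  s1 <- compute_sasa(at2, n_points = 30000L)
  expect_true(all(abs(s1$sasa - s0$sasa) / pmax(s0$sasa, 1) < 0.001))
})

test_that("PDB parsing keeps heavy chain atoms and resolves altlocs", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.800   1.200  1.00  0.00           C",
    "ATOM      6  H   ALA A   1       0.500   0.900   0.000  1.00  0.00           H",
    "HETATM    7  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "END"), pdb)
  at <- parse_structure(pdb)
  expect_equal(nrow(at), 5L)               # 5 heavy atoms, no H, no water
  expect_false(any(at$element == "H"))
  expect_error(parse_structure(pdb, chain = "B"), "available")

  alt <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       0.300   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END"), alt)
  a2 <- parse_structure(alt)
  expect_equal(nrow(a2), 2L)               # one conformer per atom name
  expect_equal(a2$x[a2$element == "N"], 0.3)  # the higher-occupancy B conformer
})

test_that("RSA normalizes by the Gly-X-Gly reference and caps at 100", {
  s <- data.frame(chain = "A", resnum = 1:3, aa = c("G", "A", "G"),
                  sasa = c(150, 64.5, 0))
  ref <- c(G = 100, A = 129)
  r <- compute_rsa(s, reference = ref)
  expect_equal(r$rsa, c(100, 50, 0))        # 150% capped; 64.5/129 = 50%; 0
  r2 <- compute_rsa(s, reference = ref, cap = Inf)
  expect_equal(r2$rsa[1], 150)
  expect_error(compute_rsa(data.frame(chain = "A", resnum = 1, aa = "W",
                                      sasa = 10), reference = ref),
               "missing")
})

test_that("the central Gly-X-Gly residue self-normalizes to 100% RSA", {
  p <- make_toy_structure("gxg_extended", "S")
  r <- compute_rsa(compute_sasa(parse_structure(p)),
                   reference = gxg_reference(c("S", "G")))
  expect_equal(r$rsa[r$resnum == 2L], 100, tolerance = 1e-6)
})

test_that("RSA modulation applies the (100 - RSA)/100 factor", {
  tab <- new_score_table(
    data.frame(position = c(1L, 1L, 2L, 3L, 4L),
               wt = "A", mt = c("C", "D", "C", "C", "C"),
               score = c(4, -2, 3, 1.5, 2)), "lorw")
  rsa <- data.frame(chain = "A", resnum = 1:3, aa = "A",
                    sasa = c(0, 120, 60), rsa = c(0, 100, 50))
  expect_message(mod <- rsa_modulate(tab, rsa), "dropped")
  expect_equal(nrow(mod), 4L)               # position 4 has no coverage
  expect_equal(mod$score[mod$position == 1L], c(4, -2))   # RSA 0: unchanged
  expect_equal(mod$score[mod$position == 2L], 0)          # RSA 100: zeroed
  expect_equal(mod$score[mod$position == 3L], 0.75)       # RSA 50, E=1.5
  expect_equal(attr(mod, "method"), "lorw_rsa")
})

test_that("modulation preserves sign, never inflates, and keeps within-position ranks", {
  set.seed(51)
  for (rep in 1:5) {
    pos <- rep(1:6, each = 8)
    tab <- new_score_table(
      data.frame(position = pos, wt = "A",
                 mt = unlist(replicate(6, sample(setdiff(AA20, "A"), 8),
                                       simplify = FALSE)),
                 score = rnorm(48, sd = 3)), "lor")
    rsa <- data.frame(chain = "A", resnum = 1:6, aa = "A", sasa = 1,
                      rsa = runif(6, 0, 99))
    mod <- rsa_modulate(tab, rsa)
    expect_true(all(sign(mod$score) == sign(tab$score)))
    expect_true(all(abs(mod$score) <= abs(tab$score) + 1e-12))
    for (p in 1:6) {
      a <- tab$score[tab$position == p]
      b <- mod$score[mod$position == p]
      expect_equal(order(a), order(b))
    }
  }
})
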