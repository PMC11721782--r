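#' Planted Potts model for synthetic alignments
#'
#' Fields are drawn i.i.d. Normal(0, field_scale); couplings are zero except
#' at the planted pairs, where the q x q block carries entries of the given
#' strength along a seeded random permutation of the states (a signed
#' permutation pattern: strong, structured coupling that survives the
#' zero-sum gauge). Deterministic given the seed.
#'
#' @param L number of sites.
#' @param q alphabet size (<= 21; states map to the first `q` symbols of
#'   [AA_ALPHABET21]).
#' @param planted_pairs matrix/data.frame with columns `i`, `j`, `strength`
#'   (1 <= i < j <= L), or NULL for an independent-site model.
#' @param field_scale sd of the fields.
#' @param seed integer seed.
#' @return an `evostab_potts` model; `attr(, "planted_pairs")` records the
#'   plant.
#' @export
make_planted_model <- function(L, q, planted_pairs = NULL, field_scale = 1,
                               seed = 1L) {
  pp <- if (is.null(planted_pairs)) NULL else as.data.frame(planted_pairs)
  if (!is.null(pp)) {
    stopifnot(all(pp$i < pp$j), all(pp$i >= 1), all(pp$j <= L))
  }
  model <- withr::with_seed(seed, {
    h <- matrix(stats::rnorm(L * q, sd = field_scale), L, q)
    J <- array(0, dim = c(q, q, L * (L - 1L) / 2L))
    if (!is.null(pp)) {
      for (k in seq_len(nrow(pp))) {
        perm <- sample(q)
        B <- matrix(0, q, q)
        B[cbind(seq_len(q), perm)] <- pp$strength[k]
        J[, , pair_index(pp$i[k], pp$j[k], L)] <- B
      }
    }
    new_potts(h, J, q = q)
  })
  attr(model, "planted_pairs") <- pp
  model
}

#' Gibbs-sample an alignment from a Potts model
#'
#' Sequential-sweep Gibbs sampling of the model's Boltzmann distribution.
#' The returned alignment has `N` rows: row 1 is the query, set to the
#' model's maximum-field sequence, and rows 2..N are draws taken after
#' `burn_in` full sweeps with `thin` sweeps between consecutive samples.
#' Reproducible by seed.
#'
#' @param model `evostab_potts` model.
#' @param N total number of alignment rows (including the query row).
#' @param burn_in warm-up sweeps (>= 1).
#' @param thin sweeps between retained samples.
#' @param seed integer seed.
#' @return an [new_alignment()]; states are the first `q` alphabet symbols.
#' @export
sample_msa <- function(model, N, burn_in = 100L, thin = 5L, seed = 1L) {
  stopifnot(burn_in >= 1L, N >= 2L)
  query <- max.col(model$h, ties.method = "first")
  X <- withr::with_seed(seed,
    gibbs_sample_cpp(model$h, as.numeric(model$J), N - 1L,
                     as.integer(burn_in), as.integer(thin),
                     as.integer(query)))
  m <- decode_states(rbind(query, X))
  rownames(m) <- NULL
  new_alignment(m, ids = c("query", paste0("s", seq_len(N - 1L))),
                query_index = 1L)
}

#' Inject redundancy clusters into an alignment
#'
#' Each sequence is expanded into `copies` rows: the original plus
#' `copies - 1` perturbed replicas with i.i.d. substitutions at the given
#' per-column rate (substitutions draw uniformly from the other amino-acid
#' states, never a gap). With rates below 0.2 the replicas stay above the
#' 80% identity threshold in expectation, exercising the redundancy
#' down-weighting. The query row remains row 1.
#'
#' @param aln alignment.
#' @param copies total rows per input sequence (>= 1).
#' @param mutation_rate per-column perturbation probability (< 0.2 advised).
#' @param seed integer seed.
#' @return alignment with `copies * N_tot` rows.
#' @export
inject_redundancy <- function(aln, copies, mutation_rate = 0, seed = 1L) {
  stopifnot(copies >= 1L, mutation_rate >= 0, mutation_rate < 1)
  if (copies == 1L && mutation_rate == 0) return(aln)
  states <- unique(as.vector(aln$matrix))
  states <- setdiff(states, "-")
  withr::with_seed(seed, {
    rows <- list(); ids <- character(0)
    for (r in seq_len(n_seq(aln))) {
      rows[[length(rows) + 1L]] <- aln$matrix[r, ]
      ids <- c(ids, aln$ids[r])
      if (copies > 1L) for (k in seq_len(copies - 1L)) {
        s <- aln$matrix[r, ]
        hit <- stats::runif(length(s)) < mutation_rate
        if (any(hit))
          s[hit] <- vapply(s[hit], function(cur)
            sample(setdiff(states, cur), 1L), character(1))
        rows[[length(rows) + 1L]] <- s
        ids <- c(ids, paste0(aln$ids[r], "_copy", k))
      }
    }
    qrow <- (match(aln$query_index, seq_len(n_seq(aln))) - 1L) * copies + 1L
    new_alignment(do.call(rbind, rows), ids = ids, query_index = qrow)
  })
}

#' Synthetic ddG table with RSA-modulated evolutionary signal
#'
#' Generates ddG = alpha * ((100 - RSA(i)) / 100) * E(i, wt, mt) + noise,
#' emulating the empirical structure that stability effects track
#' evolutionary scores more strongly in the buried core: the true signal is
#' exactly the RSA-modulated score, so with varying RSA the modulated score
#' should out-correlate the raw one.
#'
#' @param scores [new_score_table()] of "true" evolutionary scores E.
#' @param rsa [compute_rsa()] result (matched on `position == resnum`).
#' @param alpha positive signal coefficient (kcal/mol per score unit).
#' @param noise_sd Gaussian noise sd (kcal/mol).
#' @param seed integer seed.
#' @param protein protein identifier for the output rows.
#' @return data.frame `protein`, `position`, `wt`, `mt`, `ddg`.
#' @export
make_ddg <- function(scores, rsa, alpha, noise_sd, seed = 1L,
                     protein = "synthetic") {
  stopifnot(alpha > 0, noise_sd >= 0)
  idx <- match(scores$position, rsa$resnum)
  if (anyNA(idx)) stop("score positions without RSA coverage")
  fac <- (100 - rsa$rsa[idx]) / 100
  noise <- withr::with_seed(seed, stats::rnorm(nrow(scores), sd = noise_sd))
  data.frame(protein = protein, position = scores$position,
             wt = scores$wt, mt = scores$mt,
             ddg = alpha * fac * scores$score + noise,
             stringsAsFactors = FALSE)
}

# ---- toy structures -----------------------------------------------------

# place atom D from A-B-C with bond |CD|, angle B-C-D, dihedral A-B-C-D (NeRF)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Idealized toy peptide structures
#'
#' Builds a Gly-X-Gly tripeptide in extended conformation
#' (phi/psi = -120/+120 degrees) or a short alpha helix
#' (phi/psi = -57/-47) capped by glycines, from ideal backbone geometry
#' (N, CA, C, O plus a template C-beta on non-Gly residues), and writes it
#' as a PDB file. Only relative solvent accessibility is consumed
#' downstream, so full side-chain rotamers are deliberately not modeled.
#'
#' @param kind `"gxg_extended"` or `"helix"`.
#' @param x one-letter code of the guest amino acid X.
#' @param n_res helix length (ignored for the tripeptide).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
make_toy_structure <- function(kind = c("gxg_extended", "helix"), x = "A",
                               n_res = 11L, path = tempfile(fileext = ".pdb")) {
  kind <- match.arg(kind)
  if (!x %in% AA20) stop("x must be a standard amino acid")
  if (kind == "gxg_extended") {
    seq1 <- c("G", x, "G")
    phi <- rep(-120, 3); psi <- rep(120, 3)
  } else {
    stopifnot(n_res >= 4L)
    seq1 <- c("G", rep(x, n_res - 2L), "G")
    phi <- rep(-57, n_res); psi <- rep(-47, n_res)
  }
  L <- length(seq1)

  # ideal backbone geometry (Engh-Huber-like)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231; bCACB <- 1.532
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCAC0 <- 120.5

  N <- CA <- C <- O <- CB <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  th <- (180 - aNCAC) * pi / 180
  C[1, ] <- CA[1, ] + bCAC * c(cos(th), sin(th), 0)
  for (r in seq_len(L - 1L)) {
    N[r + 1L, ] <- place_atom(N[r, ], CA[r, ], C[r, ], bCN, aCACN, psi[r])
    CA[r + 1L, ] <- place_atom(CA[r, ], C[r, ], N[r + 1L, ], bNCA, aCNCA, 180)
    C[r + 1L, ] <- place_atom(C[r, ], N[r + 1L, ], CA[r + 1L, ], bCAC,
                              aNCAC, phi[r + 1L])
  }
  for (r in seq_len(L)) {
    psi_r <- if (r < L) psi[r] else 120
    ref <- if (r < L) N[r + 1L, ] else
      place_atom(N[r, ], CA[r, ], C[r, ], bCN, aCACN, psi_r)
    O[r, ] <- place_atom(ref, CA[r, ], C[r, ], bCO, aCAC0, 180)
    if (seq1[r] != "G")
      CB[r, ] <- place_atom(C[r, ], N[r, ], CA[r, ], bCACB, 110.4, 122.5)
  }

  lines <- character(0)
  serial <- 0L
  emit <- function(name, xyz, r, elem) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), "", AA1TO3[seq1[r]], "A", r, "",
            xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
  }
  for (r in seq_len(L)) {
    lines <- c(lines, emit("N", N[r, ], r, "N"), emit("CA", CA[r, ], r, "C"),
               emit("C", C[r, ], r, "C"), emit("O", O[r, ], r, "O"))
    if (seq1[r] != "G") lines <- c(lines, emit("CB", CB[r, ], r, "C"))
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
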