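#' Pairwise Potts (DCA) model
#'
#' The model assigns a sequence S = (a_1, ..., a_L) the Boltzmann probability
#' P(S) proportional to exp( sum_i h_i(a_i) + sum_{i<j} J_ij(a_i, a_j) ),
#' i.e. the inverse temperature is fixed to 1 and absorbed into the
#' parameters, and larger fields/couplings mean more probable. Couplings are
#' stored once per unordered pair i < j as q x q blocks `J[a, b, p]` with
#' `a` the state at i and `b` the state at j; the symmetric counterpart is
#' `J_ji(b, a) = J_ij(a, b)` by construction.
#'
#' @param h L x q field matrix.
#' @param J q x q x npair coupling array (npair = L(L-1)/2), pair p ordered
#'   (1,2), (1,3), ..., (L-1,L).
#' @param q alphabet size (21 for real alignments: 20 amino acids + gap).
#' @param positions 1-based query positions corresponding to model sites.
#' @param query integer codes (1..q) of the query sequence at those sites.
#' @param lambda_h,lambda_J L2 regularization strengths (per entry).
#' @param gauge `"unconstrained"` or `"zero-sum"`.
#' @return object of class `evostab_potts`.
#' @export
new_potts <- function(h, J, q = ncol(h), positions = seq_len(nrow(h)),
                      query = NULL, lambda_h = NA_real_, lambda_J = NA_real_,
                      gauge = "unconstrained") {
  L <- nrow(h)
  npair <- L * (L - 1L) / 2L
  stopifnot(ncol(h) == q, all(dim(J) == c(q, q, npair)))
  if (is.null(query)) query <- max.col(h)
  structure(list(q = as.integer(q), L = as.integer(L), h = h, J = J,
                 positions = as.integer(positions),
                 query = as.integer(query),
                 lambda_h = lambda_h, lambda_J = lambda_J, gauge = gauge,
                 converged = NA, niter = NA_integer_),
            class = "evostab_potts")
}

#' @export
print.evostab_potts <- function(x, ...) {
  cat(sprintf("evostab Potts model: L = %d, q = %d, gauge = %s\n",
              x$L, x$q, x$gauge))
  if (!is.na(x$lambda_h))
    cat(sprintf("lambda_h = %g, lambda_J = %g, converged: %s\n",
                x$lambda_h, x$lambda_J, x$converged))
  invisible(x)
}

#' Index of the unordered pair (i, j), i < j, in the coupling array
#' @param i,j 1-based site indices, `i < j`.
#' @param L number of sites.
#' @export
pair_index <- function(i, j, L) {
  stopifnot(all(i < j), all(j <= L))
  (i - 1L) * L - i * (i - 1L) / 2L + (j - i)
}

#' Coupling block J_ij as a q x q matrix (rows = states at i)
#' @param model Potts model.
#' @param i,j 1-based site indices (any order).
#' @export
coupling_block <- function(model, i, j) {
  if (i < j) model$J[, , pair_index(i, j, model$L)]
  else t(model$J[, , pair_index(j, i, model$L)])
}

encode_potts_alignment <- function(aln, q) {
  X <- encode_symbols(query_resolved(aln)$matrix)
  if (max(X) > q)
    stop("alignment contains state codes above the model alphabet size q = ", q)
  X
}

#' Weighted pseudo-log-likelihood of a Potts model, with gradient
#'
#' The sum over sequences (weighted) and sites of the log conditional
#' probabilities log P(a_i | a_-i) under the model, minus the L2 penalties
#' `lambda_h * ||h||^2 + lambda_J * ||J||^2`. The gradient is analytic and
#' exact; it is returned in the same shapes as the parameters.
#'
#' @param model Potts model (carries the lambdas; NA lambdas count as 0).
#' @param aln alignment (restricted internally to query-resolved columns).
#' @param weights [compute_weights()] result or NULL for unit weights.
#' @return list with `value`, `grad_h` (L x q), `grad_J` (q x q x npair).
#' @export
pseudo_log_likelihood <- function(model, aln, weights = NULL) {
  if (!all(is.finite(model$h)) || !all(is.finite(model$J)))
    stop("non-finite model parameters")
  X <- encode_potts_alignment(aln, model$q)
  stopifnot(ncol(X) == model$L)
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights$w
  lh <- ifelse(is.na(model$lambda_h), 0, model$lambda_h)
  lj <- ifelse(is.na(model$lambda_J), 0, model$lambda_J)
  res <- joint_pll_cpp(X, w, model$h, as.numeric(model$J), lh, lj)
  res$grad_J <- array(res$grad_J, dim = dim(model$J))
  res
}

#' Fit a Potts model by pseudo-likelihood maximization
#'
#' Standard asymmetric plmDCA construction: each site's conditional
#' distribution is fit independently by L-BFGS-B (penalized multinomial
#' logistic regression on the remaining columns, exact analytic gradients),
#' every per-site estimate is moved to the zero-sum gauge, and the two
#' asymmetric estimates of each coupling block are then averaged into a
#' symmetric J. Convergence per site is reached when the projected
#' gradient max-norm drops below `tol`; sites hitting `maxit` are recorded
#' and the model is flagged unconverged with a warning.
#'
#' @param aln alignment (query-resolved columns are used).
#' @param weights sequence weights; default plmc-style weights at 80%.
#' @param lambda_h,lambda_J L2 penalties per field / coupling entry.
#' @param q alphabet size (21; smaller for synthetic reduced alphabets).
#' @param maxit L-BFGS-B iteration cap per site.
#' @param tol projected-gradient max-norm tolerance.
#' @return an `evostab_potts` model (already in the zero-sum gauge).
#' @export
fit_potts <- function(aln, weights = NULL, lambda_h = 0.01, lambda_J = 0.01,
                      q = 21L, maxit = 400L, tol = 1e-4) {
  if (n_seq(aln) < 2L) stop("need at least 2 sequences")
  if (is.null(weights)) weights <- compute_weights(aln)
  X <- encode_potts_alignment(aln, q)
  L <- ncol(X)
  if (L < 2L) stop("need at least 2 query-resolved columns")
  w <- weights$w
  npar <- q + (L - 1L) * q * q
  # the optimizer works on the objective scaled by 1/Neff (same maximizer,
  # better conditioned: tol applies to the per-effective-sequence gradient);
  # value and gradient share one backend call per parameter vector
  scale <- 1 / sum(w)

  Ksites <- vector("list", L)
  hmat <- matrix(0, L, q)
  conv <- logical(L)
  iters <- integer(L)
  for (i in seq_len(L)) {
    cache_par <- NULL
    cache_res <- NULL
    eval_site <- function(par) {
      if (is.null(cache_par) || !identical(par, cache_par)) {
        cache_res <<- site_pll_cpp(X, w, i - 1L, par, lambda_h, lambda_J, q)
        cache_par <<- par
      }
      cache_res
    }
    fn <- function(par) -scale * eval_site(par)$value
    gr <- function(par) -scale * eval_site(par)$grad
    opt <- stats::optim(numeric(npar), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, pgtol = tol))
    conv[i] <- opt$convergence == 0L
    iters[i] <- opt$counts[1]
    hmat[i, ] <- opt$par[seq_len(q)]
    Ksites[[i]] <- array(opt$par[-seq_len(q)], dim = c(q, q, L - 1L))
  }
  if (!all(conv))
    warning(sprintf("pseudo-likelihood fit: %d/%d site fits hit the iteration cap (maxit = %d)",
                    sum(!conv), L, maxit))

  # Each site's conditional fit is identified only up to a gauge; put every
  # estimate in the zero-sum gauge (double-center the coupling blocks,
  # moving the row means into the fields) before averaging the two
  # asymmetric estimates of each pair, otherwise the average mixes gauges
  # and distorts the model's conditionals.
  other <- function(i) setdiff(seq_len(L), i)
  for (i in seq_len(L)) {
    for (jj in seq_len(L - 1L)) {
      B <- Ksites[[i]][, , jj]
      rm <- rowMeans(B); cm <- colMeans(B); mm <- mean(B)
      Ksites[[i]][, , jj] <- B - outer(rm, rep(1, q)) -
        outer(rep(1, q), cm) + mm
      hmat[i, ] <- hmat[i, ] + (rm - mm)
    }
    hmat[i, ] <- hmat[i, ] - mean(hmat[i, ])
  }
  J <- array(0, dim = c(q, q, L * (L - 1L) / 2L))
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      Kij <- Ksites[[i]][, , match(j, other(i))]
      Kji <- Ksites[[j]][, , match(i, other(j))]
      J[, , pair_index(i, j, L)] <- (Kij + t(Kji)) / 2
    }
  }
  qa <- query_resolved(aln)
  model <- new_potts(hmat, J, q = q,
                     positions = qa$column_map,
                     query = encode_symbols(
                       qa$matrix[qa$query_index, , drop = FALSE])[1, ],
                     lambda_h = lambda_h, lambda_J = lambda_J,
                     gauge = "zero-sum")
  model$converged <- all(conv)
  model$niter <- iters
  model
}

#' Transform a Potts model to the zero-sum gauge
#'
#' Applies the standard gauge fix: coupling blocks are double-centered
#' (all row and column sums zero) and the displaced mass is moved into the
#' fields, which are then zero-centered per site. Probabilities, and hence
#' all conditionals and the unpenalized pseudo-log-likelihood, are unchanged.
#'
#' @param model Potts model.
#' @return equivalent model with `gauge = "zero-sum"`.
#' @export
zero_sum_gauge <- function(model) {
  if (identical(model$gauge, "zero-sum")) return(model)
  L <- model$L; q <- model$q
  h <- model$h
  J <- model$J
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      p <- pair_index(i, j, L)
      B <- J[, , p]
      rm <- rowMeans(B); cm <- colMeans(B); mm <- mean(B)
      J[, , p] <- B - outer(rm, rep(1, q)) - outer(rep(1, q), cm) + mm
      h[i, ] <- h[i, ] + (rm - mm)
      h[j, ] <- h[j, ] + (cm - mm)
    }
  }
  h <- h - rowMeans(h)
  out <- model
  out$h <- h
  out$J <- J
  out$gauge <- "zero-sum"
  out
}

#' Site-wise conditional probabilities of a sequence under a Potts model
#'
#' @param model Potts model.
#' @param s integer state codes (1..q), length L.
#' @return L x q matrix of P(a_i = a | a_-i = s_-i).
#' @export
site_conditionals <- function(model, s) {
  L <- model$L; q <- model$q
  out <- matrix(0, L, q)
  for (i in seq_len(L)) {
    e <- model$h[i, ]
    for (j in setdiff(seq_len(L), i)) {
      e <- e + coupling_block(model, i, j)[, s[j]]
    }
    e <- e - max(e)
    out[i, ] <- exp(e) / sum(exp(e))
  }
  out
}

# ---- mutation scores -----------------------------------------------------

state_code <- function(a, q) {
  code <- match(a, AA_ALPHABET21)
  if (is.na(code) || code > q) stop("unknown state: ", a)
  code
}

#' Raw epistatic mutation effect on the query background
#'
#' Evaluates, for the substitution of residue `a` by `b` at query position
#' `i`, the field-plus-coupling difference
#' `[h_i(b) - h_i(a)] + sum_{j != i} [J_ij(b, a_j) - J_ij(a, a_j)]`
#' with `a_j` the query residues. Under this package's probability
#' convention the raw value is negative for a mutation to a rarer residue;
#' score tables apply a single global orientation flip so emitted scores are
#' positive for predicted destabilizing substitutions (see
#' [potts_score_table()]).
#'
#' @param model Potts model.
#' @param i 1-based query position (must be among `model$positions`).
#' @param a wild-type residue (must match the query) — one-letter code.
#' @param b mutant residue; the gap state is not a substitution.
#' @param query optional integer state codes overriding `model$query`.
#' @return scalar raw effect (0 when `a == b`).
#' @export
mutation_score <- function(model, i, a, b, query = NULL) {
  s <- if (is.null(query)) model$query else query
  site <- match(i, model$positions)
  if (is.na(site)) stop("position ", i, " not covered by the model")
  ca <- state_code(a, model$q)
  cb <- if (identical(b, "-")) stop("mutation to a gap is not a substitution")
        else state_code(b, model$q)
  if (s[site] != ca)
    stop(sprintf("wt %s does not match query state at position %d", a, i))
  if (ca == cb) return(0)
  d <- model$h[site, cb] - model$h[site, ca]
  for (j in setdiff(seq_len(model$L), site)) {
    B <- coupling_block(model, site, j)
    d <- d + B[cb, s[j]] - B[ca, s[j]]
  }
  d
}

#' Frobenius-norm coupling strength map
#'
#' Per-pair coupling strengths `F_ij = sqrt(sum_ab J_ij(a,b)^2)` computed in
#' the zero-sum gauge (the model is transformed first unless
#' `assume_zero_sum`). For a 21-state model the gap state is excluded by
#' default so the sum runs over the 20 x 20 amino-acid block. The average
#' product correction (APC) is available behind `apc`.
#'
#' @param model Potts model.
#' @param gap_excluded drop the gap state from the norm (21-state models).
#' @param apc apply the average product correction.
#' @param assume_zero_sum skip the gauge transform (caller guarantees it).
#' @return object of class `evostab_fmap`: list with symmetric L x L matrix
#'   `F` (zero diagonal), `positions`, and flags.
#' @export
frobenius_map <- function(model, gap_excluded = TRUE, apc = FALSE,
                          assume_zero_sum = FALSE) {
  if (!assume_zero_sum) model <- zero_sum_gauge(model)
  L <- model$L
  states <- if (model$q == 21L && gap_excluded) 1:20 else seq_len(model$q)
  F <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      B <- model$J[states, states, pair_index(i, j, L)]
      F[i, j] <- F[j, i] <- sqrt(sum(B^2))
    }
  }
  if (apc) {
    rs <- rowSums(F) / (L - 1)
    tot <- sum(F) / (L * (L - 1))
    corr <- outer(rs, rs) / tot
    diag(corr) <- 0
    F <- F - corr
    diag(F) <- 0
  }
  structure(list(F = F, positions = model$positions,
                 gauge = model$gauge,
                 gap_included = !(model$q == 21L && gap_excluded),
                 apc_applied = apc),
            class = "evostab_fmap")
}

#' Coupling-pruned epistatic mutation effect
#'
#' As [mutation_score()] but the coupling sum keeps only partner positions j
#' whose Frobenius norm `F_ij` exceeds the threshold `t`. At `t = 0` every
#' pair contributes (the full epistatic score); for `t` above the largest
#' `F_ij` the score reduces to the fields-only difference.
#'
#' @param model Potts model.
#' @param fmap [frobenius_map()] result.
#' @param t nonnegative Frobenius threshold; pairs with `F_ij > t` are kept.
#' @inheritParams mutation_score
#' @return scalar raw effect.
#' @export
pruned_mutation_score <- function(model, fmap, t, i, a, b, query = NULL) {
  stopifnot(t >= 0)
  s <- if (is.null(query)) model$query else query
  site <- match(i, model$positions)
  if (is.na(site)) stop("position ", i, " not covered by the model")
  ca <- state_code(a, model$q)
  cb <- if (identical(b, "-")) stop("mutation to a gap is not a substitution")
        else state_code(b, model$q)
  if (s[site] != ca)
    stop(sprintf("wt %s does not match query state at position %d", a, i))
  if (ca == cb) return(0)
  d <- model$h[site, cb] - model$h[site, ca]
  for (j in setdiff(seq_len(model$L), site)) {
    if (fmap$F[site, j] > t) {
      B <- coupling_block(model, site, j)
      d <- d + B[cb, s[j]] - B[ca, s[j]]
    }
  }
  d
}

#' Epistatic mutation score table over all single substitutions
#'
#' Emits (pruned) Potts mutation effects for every non-wild-type amino acid
#' at every model position, in the global "positive = predicted
#' destabilizing" orientation: the raw field/coupling difference (which is
#' negative for mutations to rarer residues) is multiplied by -1 before
#' emission; the flip is recorded in `attr(, "orientation_sign")`.
#'
#' @param model Potts model.
#' @param fmap optional [frobenius_map()]; required when `t > 0`.
#' @param t Frobenius pruning threshold; 0 keeps all couplings.
#' @return an [new_score_table()] with method `"potts"` or `"potts-pruned"`.
#' @export
potts_score_table <- function(model, fmap = NULL, t = 0) {
  mut_states <- seq_len(if (model$q == 21L) 20L else model$q)
  prune <- t > 0 || !is.null(fmap)
  if (prune && is.null(fmap)) fmap <- frobenius_map(model)
  rows <- lapply(seq_len(model$L), function(site) {
    wt_code <- model$query[site]
    wt <- AA_ALPHABET21[wt_code]
    pos <- model$positions[site]
    mts <- setdiff(mut_states, wt_code)
    sc <- vapply(mts, function(cb) {
      b <- AA_ALPHABET21[cb]
      if (prune) pruned_mutation_score(model, fmap, t, pos, wt, b)
      else mutation_score(model, pos, wt, b)
    }, numeric(1))
    data.frame(position = pos, wt = wt, mt = AA_ALPHABET21[mts],
               score = -sc)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  out <- new_score_table(df, if (prune) "potts-pruned" else "potts")
  attr(out, "orientation_sign") <- -1
  attr(out, "frobenius_threshold") <- if (prune) t else NA_real_
  out
}
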