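# Bondi van der Waals radii (Angstrom), element-keyed
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Theoretical maximum accessible surface areas (Tien et al. 2013)
#'
#' Per-residue maximal solvent-accessible surface areas (Angstrom^2) of X in
#' an extended Gly-X-Gly tripeptide, theoretical values. Used as the default
#' normalization for relative solvent accessibility.
#'
#' @format Named numeric vector over the 20 one-letter amino-acid codes.
#' @export
MAX_ASA_TIEN2013 <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174)

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' Parse the heavy atoms of one chain of a PDB file
#'
#' Reads ATOM records with bio3d, keeps heavy (non-hydrogen) atoms of the
#' requested chain, drops waters and heteroatoms, and resolves alternate
#' locations by keeping the highest-occupancy conformer of each atom.
#' Van der Waals radii are assigned per element from the Bondi set.
#'
#' @param path PDB file.
#' @param chain chain identifier; default: the first chain in the file.
#' @return data.frame of class `evostab_atoms` with columns `element`, `x`,
#'   `y`, `z`, `radius`, `chain`, `resnum`, `aa` (one-letter).
#' @export
parse_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain ", chain, " not found; available: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]

  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- substr(gsub("[0-9]", "", trimws(at$elety[miss])), 1, 1)
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("no heavy atoms in chain ", chain)

  # altloc: keep the highest-occupancy conformer per (resnum, atom name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$elety)
  ord <- order(key, -occ, alt)
  dup <- duplicated(key[ord])
  sel <- ord[!dup]
  sel <- sort(sel)
  at <- at[sel, , drop = FALSE]
  elem <- elem[sel]

  radius <- unname(VDW_RADII[elem])
  if (anyNA(radius)) {
    warning("unknown element(s) ", paste(unique(elem[is.na(radius)]), collapse = ", "),
            "; using radius 1.70")
    radius[is.na(radius)] <- 1.70
  }
  aa <- unname(AA3TO1[at$resid])
  structure(data.frame(element = elem, x = at$x, y = at$y, z = at$z,
                       radius = radius, chain = at$chain, resnum = at$resno,
                       aa = aa, stringsAsFactors = FALSE),
            class = c("evostab_atoms", "data.frame"))
}

# Deterministic, nearly uniform unit sphere points (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic rolling-probe surface: each atom's sphere of radius
#' `radius + probe` is sampled with a Fibonacci point lattice, and the
#' accessible fraction (points outside every neighbor's probe-expanded
#' sphere) scales the analytic sphere area. Per-atom areas are summed per
#' residue.
#'
#' @param atoms [parse_structure()]-style data.frame.
#' @param probe probe (water) radius in Angstrom.
#' @param n_points sample points per atom (>= 100).
#' @return data.frame (`chain`, `resnum`, `aa`, `sasa`) with attributes
#'   `probe` and `n_points`.
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  stopifnot(n_points >= 100L)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (anyDuplicated(round(xyz, 6)))
    warning("atoms with identical coordinates present")
  pts0 <- fibonacci_sphere(n_points)
  R <- atoms$radius + probe
  sasa_atom <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < R[i] + R & seq_len(n) != i)
    area <- 4 * pi * R[i]^2
    if (length(nb) == 0L) {
      sasa_atom[i] <- area
      next
    }
    pts <- sweep(pts0 * R[i], 2, xyz[i, ], "+")
    acc <- points_accessible_cpp(pts, xyz[nb, , drop = FALSE], R[nb]^2)
    sasa_atom[i] <- area * mean(acc)
  }
  agg <- stats::aggregate(sasa_atom,
                          by = list(chain = atoms$chain, resnum = atoms$resnum),
                          FUN = sum)
  ord <- order(agg$resnum)
  agg <- agg[ord, ]
  aa <- atoms$aa[match(paste(agg$chain, agg$resnum),
                       paste(atoms$chain, atoms$resnum))]
  out <- data.frame(chain = agg$chain, resnum = agg$resnum, aa = aa,
                    sasa = agg$x, stringsAsFactors = FALSE)
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  out
}

#' Relative solvent accessibility
#'
#' RSA = 100 * SASA / reference(aa), the reference being the residue's
#' maximal accessibility in an extended Gly-X-Gly tripeptide. Values above
#' the cap (default 100%, e.g. from terminal residues) are capped so the
#' downstream modulation factor stays in [0, 1]; `cap = Inf` disables it.
#'
#' @param sasa [compute_sasa()] result.
#' @param reference named numeric vector of per-amino-acid maximal ASA
#'   (Angstrom^2); default [MAX_ASA_TIEN2013].
#' @param cap upper cap on RSA (percent).
#' @return data.frame of class `evostab_rsa` (`chain`, `resnum`, `aa`,
#'   `sasa`, `rsa`).
#' @export
compute_rsa <- function(sasa, reference = MAX_ASA_TIEN2013, cap = 100) {
  ref <- reference[sasa$aa]
  if (anyNA(ref))
    stop("residue type(s) missing from the reference table: ",
         paste(unique(sasa$aa[is.na(ref)]), collapse = ", "))
  rsa <- 100 * sasa$sasa / unname(ref)
  rsa <- pmin(rsa, cap)
  out <- sasa
  out$rsa <- rsa
  attr(out, "reference") <- deparse(substitute(reference))
  class(out) <- c("evostab_rsa", "data.frame")
  out
}

#' Modulate an evolutionary score table by relative solvent accessibility
#'
#' Applies `RSA*E(i, wt, mt) = ((100 - RSA(i)) / 100) * E(i, wt, mt)`:
#' fully exposed positions are zeroed, fully buried ones keep their score.
#' The common positive factor preserves the sign of E and the within-position
#' ranking of mutants, and never increases a score's magnitude. Positions
#' without structure coverage are dropped with a message.
#'
#' @param scores [new_score_table()] table.
#' @param rsa [compute_rsa()] result; matched on `position == resnum`.
#' @return score table with method label suffixed `"_rsa"`.
#' @export
rsa_modulate <- function(scores, rsa) {
  idx <- match(scores$position, rsa$resnum)
  drop <- is.na(idx)
  if (any(drop))
    message(sum(drop), " score rows dropped: position without structure coverage")
  out <- scores[!drop, , drop = FALSE]
  fac <- (100 - rsa$rsa[idx[!drop]]) / 100
  out$score <- fac * out$score
  out <- new_score_table(out, paste0(attr(scores, "method"), "_rsa"))
  attr(out, "orientation_sign") <- attr(scores, "orientation_sign")
  out
}

#' Self-consistent Gly-X-Gly reference accessibility
#'
#' Computes, with this package's own SASA routine and toy extended
#' Gly-X-Gly fixtures (backbone + C-beta side chains), the central-residue
#' accessibility for a set of amino acids. Using this as the reference table
#' makes RSA of the package's synthetic structures exactly self-normalized.
#'
#' @param aas amino acids (one-letter) to tabulate.
#' @param probe,n_points forwarded to [compute_sasa()].
#' @return named numeric vector (Angstrom^2).
#' @export
gxg_reference <- function(aas = AA20, probe = 1.4, n_points = 960L) {
  vapply(aas, function(x) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    make_toy_structure("gxg_extended", x, path = path)
    s <- compute_sasa(parse_structure(path), probe = probe,
                      n_points = n_points)
    s$sasa[s$resnum == 2L]
  }, numeric(1))
}
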