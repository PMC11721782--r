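---
title: "Evolutionary scoring of mutational stability effects: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary scoring of mutational stability effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`evostab` extracts unsupervised mutation-effect scores from multiple
sequence alignments (MSAs) of protein homologs, modulates them with a
structural burial term, and evaluates them against experimental stability
changes (ΔΔG, kcal/mol, positive = destabilizing). This vignette is the
package's own account of the underlying models, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
establish.

## The scientific setting

Folding stability constrains protein evolution: substitutions that are
strongly destabilizing are purged, so residues that matter for stability
look conserved in an alignment of homologs. Reading this signal back out is
complicated by three things that the package addresses explicitly:

1. **Phylogenetic redundancy.** MSAs contain clusters of near-identical
   sequences, so raw counts overweight densely sampled clades.
2. **Epistasis.** The effect of a substitution can depend on the residues
   at contacting positions, which motivates pairwise (Potts) models over
   per-column ones — but pairwise couplings are notoriously noisy to infer.
3. **Structure.** Mutations in the buried core are systematically more
   destabilizing than at the exposed surface, and surface columns of an MSA
   are gappy and weakly conserved, so a purely evolutionary score
   overcalls destabilization at exposed positions.

## Sequence weights and Neff

Every sequence j receives weight `w_j = 1/m_j`, with `m_j` the number of
alignment members (including j) at ≥ 80% identity to it;
`Neff = Σ_j w_j`. Identity is computed over the full alignment length with
the gap as an ordinary 21st symbol (a gap aligned to a gap counts as a
match), matching the plmc convention; a switch excludes double-gap columns
for sensitivity analyses. The threshold comparison is inclusive (`>=`).
Exact duplicates share one unit of weight, so Neff is invariant under
duplicating every sequence — the package's weight tests assert this exactly,
and also compare the compiled implementation against a brute-force
O(N²L) double loop.

## Independent-site scores

Positional frequencies are computed over 21 states (20 amino acids + gap)
and regularized as

    f̄_i(a) = f_i(a) (1 − θ) + θ/21,      θ = 0.01 by default,

which keeps rows normalized and every state strictly positive. With a
weight vector, counts are weight-rectified first
(`f_i^w(a) = Σ_j w_j δ(a, a_ij) / Σ_j w_j`) and the same regularization is
applied to the weighted frequencies. The scores are:

- `CI(i) = sqrt(½ Σ_{a∈20} (f̄_i(a) − f̄(a))²)` — conservation relative to
  the alignment-wide background `f̄(a)` (computed over all columns of the
  curated MSA by default; the gap participates in normalization but not in
  the sum);
- `LOR(i, wt, mt) = logit f̄_i(wt) − logit f̄_i(mt)` with the natural log —
  the base is irrelevant downstream because evaluation is rank-based, and
  is fixed for reproducibility;
- `LORw`: LOR on the weighted frequencies.

Mutant states range over the 20 amino acids only; the gap is never a
mutant. A frequency of exactly 1 (possible only at θ = 0) raises an error
pointing at the regularization rather than returning an infinite logit.
All score tables carry the orientation "positive = predicted
destabilizing", so a frequent wild type mutated to a rare residue scores
positive.

## The Potts model and its inference

Sequences are modeled as draws from

    P(S) ∝ exp( Σ_i h_i(a_i) + Σ_{i<j} J_ij(a_i, a_j) ),

the inverse temperature being fixed at 1 and absorbed into the parameters
(only relative scores matter for rank evaluation). Fitting maximizes the
weighted pseudo-likelihood — the sum over sequences and sites of
`log P(a_i | a_-i)` — minus L2 penalties `λ_h‖h‖² + λ_J‖J‖²`
(defaults 0.01 per entry, both exposed as scan parameters since no single
strength is optimal for every protein). The implementation follows the
standard asymmetric plmDCA construction: each site's conditional is an
independent penalized multinomial logistic regression (analytic gradients
in compiled code, L-BFGS-B, convergence at projected-gradient max-norm
below `tol`), and the two asymmetric estimates of each coupling block are
averaged. One numerical point deserves emphasis: each per-site fit is
identified only up to a gauge, so both estimates are moved to the zero-sum
gauge (coupling blocks double-centered, displaced mass moved into the
fields) *before* averaging — averaging estimates in different gauges
produces a model that is equivalent to neither and visibly distorts its
conditionals. For the optimizer the objective is scaled by 1/Neff, which
leaves the maximizer unchanged and makes the gradient tolerance a
per-effective-sequence quantity.

The substitution score is the Eq.-style field-plus-coupling difference on
the query background,

    ΔX(i, a→b) = [h_i(b) − h_i(a)] + Σ_{j≠i} [J_ij(b, a_j) − J_ij(a, a_j)],

computed exactly in this form and then flipped by a single global sign at
score-table emission so that mutations toward rarer residues score
positive, consistent with every other method in the package. The flip is
recorded in the table metadata (`orientation_sign`).

Coupling strength between positions is summarized by the Frobenius norm
`F_ij` of the zero-sum-gauge coupling block over the 20×20 amino-acid
states (gap excluded by default; an APC correction is available behind a
flag but off by default). The pruned epistatic score keeps only partners
with `F_ij > t`: at `t = 0` it is the full epistatic score, above
`max F_ij` it degenerates to the fields-only score, and in between the set
of contributing pairs is nested as `t` decreases. `t` is exposed as a scan
parameter; no packaged default is claimed to be optimal.

## Structure: SASA, RSA, and score modulation

Per-residue solvent-accessible surface area uses a deterministic
Shrake–Rupley scheme: each atom's probe-expanded sphere (probe 1.4 Å,
Bondi van der Waals radii) is sampled with a Fibonacci point lattice
(960 points per atom by default) and the accessible fraction scales the
analytic sphere area. The lattice is fixed in space, so rotation invariance
holds to the sampling resolution — the tests assert 0.1% agreement using a
dense converged lattice, and 1% agreement of an isolated atom with the
closed form 4π(r + probe)². Relative solvent accessibility divides by the
residue's maximal accessibility in an extended Gly-X-Gly tripeptide; the
packaged default reference is the published theoretical table of Tien et
al. (2013), user tables are accepted, and `gxg_reference()` computes a
self-consistent reference with the package's own SASA routine on its own
toy fixtures (which carry backbone + Cβ only). RSA is capped at 100% by
default so the modulation factor stays in [0, 1].

Any score table is modulated as

    RSA⊙E(i, wt, mt) = ((100 − RSA(i))/100) · E(i, wt, mt),

zeroing fully exposed positions and preserving buried ones. The factor is
common and nonnegative within a position, so within-position mutant
rankings, signs, and score magnitudes are never inflated. The core/surface
boundary used in stratified evaluation is RSA 20% (core strictly below;
the boundary residue counts as surface).

## Evaluation protocol

Per protein and method, Spearman ρ (average ranks for ties — the
convention had to be fixed somewhere, and average ranks is the standard)
between scores and ΔΔG on their matched mutations; then the unweighted
mean of per-protein ρ, overall, within Neff bins ([10,100), [100,1000),
[1000,10000), [10000,∞), plus a below-10 catch bin so bins partition the
proteins), and per core/surface stratum when RSA is supplied. Proteins with
fewer than 3 matched mutations are excluded with a message (ρ is degenerate
below that), as are constant score vectors. The bin-weighted mean of bin
means equals the overall mean by construction, which the tests assert. A
bootstrap-over-proteins comparison of methods is deliberately not dressed
up as the original significance procedure; it is not implemented here.

## Synthetic data: what it emulates and what it does not

The generator produces (a) MSAs Gibbs-sampled from Potts models with known
fields and planted coupling blocks (sequential sweeps, burn-in 100, thin 5,
validated against exhaustively enumerated Boltzmann probabilities on tiny
models where the partition function is computable); (b) redundancy
clusters (each sequence replicated with i.i.d. perturbations below the
identity threshold) to exercise the reweighting; (c) idealized toy
structures — extended Gly-X-Gly tripeptides (φ/ψ = −120°/120°) and
α-helices (−57°/−47°) built from ideal backbone geometry with Cβ-only side
chains, sufficient because only relative accessibility is consumed; and
(d) ΔΔG tables generated as `α · ((100 − RSA)/100) · E + noise` — the true
signal is exactly the RSA-modulated score, emulating the empirical pattern
that stability effects track evolutionary preference most strongly in the
buried core. Defaults α = 1 and noise sd 0.5 kcal/mol put the noise at
roughly half the signal spread, a moderate-noise regime comparable to
scatter in real stability data.

Everything is seed-deterministic. The study-scale problem sizes used by the
tests and the acceptance script are: planted-coupling recovery at N = 5000
sequences, L = 30, q = 8 with three planted pairs of strength 1.0 across
five seeds; sampler/enumeration checks at N = 20,000 on L ≤ 3, q ≤ 3;
the scoring pipeline on 13-residue helices with N = 400-sequence MSAs.

What passing these tests shows: the estimators are implemented correctly
(weights match brute force; gradients match finite differences; the
sampler matches enumeration; planted couplings are recovered; the RSA
modulation provably helps when the generative process is RSA-modulated).
What they do not show: performance on real proteins. Synthetic MSAs have no
phylogenetic tree structure (redundancy clusters are star-shaped, not
nested), no alignment errors, no gap structure correlated with loops, and
the synthetic ΔΔG shares its functional form with one of the scores being
evaluated, which flatters the modulated score by construction. Claims
about real-data ranking of methods require real MSAs, structures and
measurements.

## Known limitations and open choices

- Stockholm parsing covers the plain single/multi-block sequence format
  (annotation lines skipped), not full feature markup.
- The SASA routine is a generic rolling-probe implementation, not a DSSP
  extension; RSA values therefore differ in detail from DSSP-family tools,
  which is acceptable downstream because only rank-preserving modulation
  is consumed. The reference-table choice is logged in the output
  attributes.
- Nonstandard residues (B, Z, X, U, O, J) map to the gap state by default
  to keep 21-state normalization exact; the mapping is configurable.
- `fit_potts` regularization defaults are honest defaults, not tuned
  optima; the per-entry penalty is applied to the summed (unnormalized)
  pseudo-likelihood, so its effective strength relative to the data shrinks
  as Neff grows — scan `lambda_J` when coupling quality matters.
- MSA curation thresholds (gap ratio, query identity) ship unset: they are
  exposed as filters with no defaults because no universally good values
  exist.
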