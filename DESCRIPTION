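Package: evostab
Title: Evolutionary Scoring of Protein Mutational Stability Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised scoring of amino-acid substitutions from protein
    multiple sequence alignments, and its evaluation against experimental
    stability changes. Implements plmc-style sequence reweighting and the
    effective sequence number Neff, regularized (weighted) positional
    frequency models with the independent-site scores CI, LOR and LORw,
    pairwise Potts model inference by pseudo-likelihood maximization with
    Frobenius-norm coupling pruning, relative solvent accessibility from a
    deterministic Shrake-Rupley surface computation with RSA-modulated
    scores, a per-protein Spearman evaluation protocol with Neff binning and
    core/surface stratification, and a synthetic-data module (Gibbs-sampled
    Potts alignments, redundancy injection, RSA-dependent synthetic ddG
    tables, idealized toy structures) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
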