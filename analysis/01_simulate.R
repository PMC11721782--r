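#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# A Potts model with three planted couplings (L = 30, q = 8) provides an MSA
# sampled from its Boltzmann distribution; an idealized 13-residue helix
# provides a structure with varying burial; the generating model's own
# substitution effects, RSA-modulated plus Gaussian noise, provide a
# synthetic "experimental" ddG table. Everything downstream (weights,
# site scores, Potts refits, RSA, evaluation) runs off these files.

suppressPackageStartupMessages(library(evostab))
dir.create("results", showWarnings = FALSE)
seed <- 2024L

## coupled MSA for coevolution analyses
planted <- data.frame(i = c(3, 10, 22), j = c(17, 25, 28), strength = 1.0)
model <- make_planted_model(L = 30, q = 8, planted_pairs = planted,
                            field_scale = 0.5, seed = seed)
msa <- sample_msa(model, N = 5000, seed = seed + 1L)
write_alignment(msa, "results/planted_msa.fasta")
message("wrote results/planted_msa.fasta: ", n_seq(msa), " x ", n_col(msa))

## redundancy-injected variant (on a 1000-sequence subsample) for the
## weighting analysis
red <- inject_redundancy(subsample_msa(msa, 1000, seed = seed + 9L),
                         copies = 3, mutation_rate = 0.03,
                         seed = seed + 2L)
write_alignment(red, "results/planted_msa_redundant.fasta")

## independent-site MSA (20 amino-acid states, gap-free) for the scoring
## pipeline: every query position stays resolved and scoreable
gen <- make_planted_model(L = 13, q = 20, planted_pairs = NULL,
                          field_scale = 1.2, seed = seed + 3L)
aln13 <- sample_msa(gen, N = 400, seed = seed + 4L)
write_alignment(aln13, "results/site_msa.fasta")

## structure and ddG
make_toy_structure("helix", "A", n_res = 13, path = "results/helix13.pdb")
rsa <- compute_rsa(compute_sasa(parse_structure("results/helix13.pdb")),
                   reference = gxg_reference(c("A", "G")))
truth <- potts_score_table(gen)
ddg <- make_ddg(truth, rsa, alpha = 1, noise_sd = 0.5, seed = seed + 5L,
                protein = "synth1")
utils::write.table(ddg, "results/ddg_synthetic.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/ddg_synthetic.tsv: ", nrow(ddg), " mutations, ",
        "mean ddG ", round(mean(ddg$ddg), 3), " kcal/mol")

## ground truth manifest
jsonlite::write_json(
  list(seed = seed, planted_pairs = planted,
       ddg = list(alpha = 1, noise_sd = 0.5),
       msa = list(L = 30, q = 8, N = 5000),
       site_msa = list(L = 13, q = 20, N = 400)),
  "results/ground_truth.json", auto_unbox = TRUE, digits = NA)
message("wrote results/ground_truth.json")
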