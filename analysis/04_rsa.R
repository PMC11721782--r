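#!/usr/bin/env Rscript
# Stage 4: solvent accessibility and RSA-modulated scores.
#
# Computes per-residue SASA/RSA of the helix structure (against the
# self-consistent Gly-X-Gly extended reference) and applies the
# (100 - RSA)/100 modulation to every score table from stages 2-3.

suppressPackageStartupMessages(library(evostab))

rsa <- compute_rsa(compute_sasa(parse_structure("results/helix13.pdb")),
                   reference = gxg_reference(c("A", "G")))
utils::write.table(rsa, "results/rsa_helix13.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("helix RSA: median %.1f%% (core positions: %s)",
                stats::median(rsa$rsa),
                paste(rsa$resnum[rsa$rsa < 20], collapse = " ")))

read_scores <- function(path) {
  hdr <- readLines(path, n = 1)
  method <- sub(".*method=(\\S+).*", "\\1", hdr)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  df$mt <- as.character(df$mt)
  new_score_table(df, method)
}
for (m in c("lor", "lorw", "potts")) {
  tab <- read_scores(sprintf("results/scores_%s.tsv", m))
  write_score_table(rsa_modulate(tab, rsa),
                    sprintf("results/scores_%s_rsa.tsv", m))
}
message("wrote results/rsa_helix13.tsv and results/scores_*_rsa.tsv")
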