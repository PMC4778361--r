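#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the screen's input structure: a floral-bud-sized proteome
# sampled by 4 wild-type and 5 mutant label-free MS runs (the fifth mutant
# run reduced-input and excluded from quantification), a 4 + 3 replicate
# expression matrix with planted >= 2-fold DE genes, and promoter sets
# with a planted G-box. Every planted entity is written to a truth file so
# later stages can be audited.

suppressPackageStartupMessages(library(ubiscreen))
library(Biostrings)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260926)

proteome <- generate_proteome(cfg)
writeXStringSet(proteome, file.path(out, "proteome.fasta"))

runs <- simulate_runs(proteome, cfg)
for (nm in names(runs$reports)) {
  write_run_report(runs$reports[[nm]], file.path(out, paste0(nm, ".tsv")))
}
write_id_list(runs$truth, file.path(out, "truth_substrates.txt"))

expr <- generate_expression(cfg)
write_expression_matrix(expr$matrix, file.path(out, "expression.tsv"))
write_id_list(expr$probe_map, file.path(out, "probe_map.txt"))
write_id_list(expr$de_truth, file.path(out, "truth_de_genes.txt"))

prom <- generate_promoters(cfg)
writeXStringSet(prom$query, file.path(out, "promoters_query.fasta"))
writeXStringSet(prom$background, file.path(out, "promoters_background.fasta"))

n_det <- vapply(runs$reports, nrow, integer(1))
cat(sprintf("proteome: %d proteins (%d planted substrates)\n",
            length(proteome), length(runs$truth)))
cat("detections per run (before FDR filtering):\n")
print(n_det)
cat(sprintf("expression: %d probed genes x %d samples, %d planted DE\n",
            nrow(expr$matrix), ncol(expr$matrix), length(expr$de_truth)))
cat(sprintf("promoters: %d query / %d background, motif %s at rate %.2f\n",
            length(prom$query), length(prom$background),
            cfg$planted_motif, cfg$planted_motif_rate))
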