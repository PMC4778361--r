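#!/usr/bin/env Rscript
# Stage 4: differential expression and the transcript-level exclusion
# filter.
#
# Calls DE genes (>= 2-fold and p < 0.05, equal-variance t-test, raw
# p-values) on the simulated expression matrix, maps each classified
# protein to its gene's transcript status, and keeps as protein-level
# candidates those whose transcripts are unchanged: accumulation that
# transcription cannot explain, the signature of a degradation substrate.

suppressPackageStartupMessages(library(ubiscreen))

sim <- "results/sim"
sets <- "results/sets"
out <- "results/candidates"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mat <- read_expression_matrix(file.path(sim, "expression.tsv"))
groups <- ifelse(startsWith(colnames(mat), "wt"), "wild_type", "mutant")
probe_map <- read_id_list(file.path(sim, "probe_map.txt"))

de <- differential_expression(mat, groups, fold_cutoff = 2, alpha = 0.05)
write.table(de, file.path(out, "differential_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("DE genes: %d up, %d down of %d probed\n",
            sum(de$status == "up"), sum(de$status == "down"), nrow(de)))
truth_de <- read_id_list(file.path(sim, "truth_de_genes.txt"))
called <- de$gene_id[de$status != "unchanged"]
cat(sprintf("planted DE genes recovered: %d of %d probed\n",
            sum(intersect(truth_de, de$gene_id) %in% called),
            length(intersect(truth_de, de$gene_id))))

only <- read_id_list(file.path(sets, "mutant_only.txt"))
higher <- read_id_list(file.path(sets, "mutant_higher.txt"))
classes <- data.frame(
  protein_id = c(only, higher),
  class = rep(c("mutant_only", "mutant_higher"),
              c(length(only), length(higher))),
  stringsAsFactors = FALSE)
statuses <- transcript_status(classes$protein_id, de, probe_map)
acc <- candidate_accounting(classes, statuses)
write.table(acc$table, file.path(out, "candidate_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(acc$summary, file.path(out, "candidate_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("per-class accounting (total = no_probe + DE-excluded + candidates):\n")
print(acc$summary)
cands <- acc$table$protein_id[acc$table$protein_level_candidate]
write_id_list(sort(cands), file.path(out, "candidates.txt"))

truth <- read_id_list(file.path(sim, "truth_substrates.txt"))
cat(sprintf("protein-level candidates: %d; recall of planted substrates %.2f, precision %.2f\n",
            length(cands), mean(truth %in% cands), mean(cands %in% truth)))
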