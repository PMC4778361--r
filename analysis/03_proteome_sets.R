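#!/usr/bin/env Rscript
# Stage 3: proteome set comparisons.
#
# Merges replicate runs into non-redundant genotype proteomes under the
# local FDR < 1 % filter, reports the replicate-overlap partition (how
# many proteins each number of runs detected), builds the pooled
# wild-type reference, and classifies mutant-only and mutant-higher
# (>= 1.5-fold) proteins.

suppressPackageStartupMessages(library(ubiscreen))

sim <- "results/sim"
quant <- "results/quant"
out <- "results/sets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

report_files <- list.files(sim, pattern = "^(wt|mut)_[0-9]+\\.tsv$",
                           full.names = TRUE)
reports <- lapply(report_files, read_run_report)
genotype <- vapply(reports, function(r) attr(r, "genotype"), character(1))
in_quant <- vapply(reports, function(r)
  isTRUE(attr(r, "include_in_quant")), logical(1))

wt_prot <- merge_runs(reports[genotype == "wild_type"], label = "wild_type")
mut_prot <- merge_runs(reports[genotype == "mutant"], label = "mutant")
write_id_list(wt_prot$members, file.path(out, "proteome_wild_type.txt"))
write_id_list(mut_prot$members, file.path(out, "proteome_mutant.txt"))
cat(sprintf("merged proteomes: %d wild-type, %d mutant (FDR < 1%%)\n",
            length(wt_prot$members), length(mut_prot$members)))

part_wt <- overlap_partition(reports[genotype == "wild_type"])
part_mut <- overlap_partition(reports[genotype == "mutant" & in_quant])
write.table(part_wt, file.path(out, "overlap_wild_type.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(part_mut, file.path(out, "overlap_mutant.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wild-type replicate overlap (runs: count, % of merged):\n")
print(part_wt)

# no previously published lists in the simulated study; the pooled
# reference therefore equals the in-house wild-type proteome
pooled <- pool_wildtype(wt_prot, list())
cat(sprintf("pooled wild type: %d proteins, own contribution %s\n",
            pooled$pooled_size,
            format_pct(pooled$own_size, pooled$pooled_size)))

only <- mutant_only(mut_prot, pooled)
write_id_list(only, file.path(out, "mutant_only.txt"))

mean_wt <- read.delim(file.path(quant, "mean_abundance_wild_type.tsv"))
mean_mut <- read.delim(file.path(quant, "mean_abundance_mutant.tsv"))
both <- merge(mean_mut, mean_wt, by = "protein_id",
              suffixes = c("_mut", "_wt"))
both <- both[!(both$protein_id %in% only), ]
higher <- sort(both$protein_id[
  classify_higher(both$mean_abundance_mut, both$mean_abundance_wt, 1.5)])
write_id_list(higher, file.path(out, "mutant_higher.txt"))

cat(sprintf("mutant-only: %d proteins; mutant-higher (>= 1.5-fold): %d\n",
            length(only), length(higher)))
truth <- read_id_list(file.path(sim, "truth_substrates.txt"))
cat(sprintf("planted substrates among them: %d of %d\n",
            sum(truth %in% c(only, higher)), length(truth)))
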