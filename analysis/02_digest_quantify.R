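#!/usr/bin/env Rscript
# Stage 2: in-silico tryptic digestion and spectral-counting normalization.
#
# Digests every protein (cut after K/R unless followed by P, no missed
# cleavages, peptides >= 6 residues), then converts each run's spectral
# counts into normalized relative abundances A = (s/S)/(t/T) and averages
# them per genotype over the runs in which each protein was detected.
# Run reports are FDR-filtered (< 1 %) before quantification; the
# reduced-input mutant test run is excluded by its include_in_quant flag.

suppressPackageStartupMessages(library(ubiscreen))
library(Biostrings)

sim <- "results/sim"
out <- "results/quant"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

proteome <- readAAStringSet(file.path(sim, "proteome.fasta"))
digest <- theoretical_counts(proteome)
write.table(digest$counts, file.path(out, "theoretical_peptides.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("digest: %d proteins, %d theoretical peptides (mean %.1f per protein)\n",
            nrow(digest$counts), digest$total,
            digest$total / nrow(digest$counts)))

report_files <- list.files(sim, pattern = "^(wt|mut)_[0-9]+\\.tsv$",
                           full.names = TRUE)
reports <- lapply(report_files, read_run_report)
names(reports) <- sub("\\.tsv$", "", basename(report_files))

fdr_filter <- function(r) {
  keep <- r$local_fdr_pct < 1
  out <- r[keep, , drop = FALSE]
  for (a in c("run_id", "genotype", "include_in_quant"))
    attr(out, a) <- attr(r, a)
  out
}
tabs <- lapply(reports, function(r) normalize_run(fdr_filter(r), digest))
for (nm in names(tabs)) {
  write.table(tabs[[nm]]$abundance,
              file.path(out, paste0("abundance_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

genotype <- vapply(reports, function(r) attr(r, "genotype"), character(1))
mean_wt <- average_abundance(tabs[genotype == "wild_type"])
mean_mut <- average_abundance(tabs[genotype == "mutant"])
write.table(mean_wt, file.path(out, "mean_abundance_wild_type.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mean_mut, file.path(out, "mean_abundance_mutant.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("quantified %d wild-type and %d mutant proteins (genotype means)\n",
            nrow(mean_wt), nrow(mean_mut)))
excluded <- names(reports)[!vapply(reports, function(r)
  isTRUE(attr(r, "include_in_quant")), logical(1))]
cat("runs excluded from quantification:",
    if (length(excluded)) paste(excluded, collapse = ", ") else "none", "\n")
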