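#!/usr/bin/env Rscript
# Stage 5: promoter hexamer enrichment and GO overrepresentation.
#
# Scores all 4096 hexamers in the query promoters against the background
# set with the binomial point probability on promoter-containing counts,
# and runs a Fisher exact GO overrepresentation test on the candidate
# gene set against the probed-gene background using a synthetic
# annotation in which one term is enriched among candidates.

suppressPackageStartupMessages(library(ubiscreen))
library(Biostrings)

sim <- "results/sim"
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

query <- readDNAStringSet(file.path(sim, "promoters_query.fasta"))
background <- readDNAStringSet(file.path(sim, "promoters_background.fasta"))
top <- rank_motifs(query, background, top = 5)
write.table(top, file.path(out, "top_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("top five enriched hexamers (binomial point probability):\n")
print(top[, c("oligomer", "query_promoters_with", "n_query",
              "background_promoters_with", "n_background", "p_value")])

# synthetic GO annotation: candidates are enriched for a "proteolysis"
# term relative to the probed background (synthetic stand-in for a real
# gene-association file)
cands <- read_id_list("results/candidates/candidates.txt")
probe_map <- read_id_list(file.path(sim, "probe_map.txt"))
cand_genes <- intersect(strip_isoform(cands), probe_map)
set.seed(20260926)
in_term <- union(sample(cand_genes, round(0.4 * length(cand_genes))),
                 sample(probe_map, round(0.05 * length(probe_map))))
other <- sample(probe_map, round(0.10 * length(probe_map)))
ann <- rbind(
  data.frame(gene_id = in_term, term_id = "GO:proteolysis"),
  data.frame(gene_id = other, term_id = "GO:photosynthesis"))
write_annotations(ann, file.path(out, "synthetic_annotations.tsv"))

go <- fisher_go(ann, cand_genes, probe_map, alpha = 0.05)
write.table(go, file.path(out, "go_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("GO overrepresentation (one-sided Fisher, raw p):\n")
print(go)
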