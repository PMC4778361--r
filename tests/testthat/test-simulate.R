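test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(planted_de_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(substrate_fold = 0.5), "fold")
  expect_error(simulation_config(protein_length_range = c(100, 50)), "length range")
  expect_error(simulation_config(promoter_length = 4), "shorter")
  expect_error(simulation_config(planted_motif = "CACGUG"), "ACGT")
})

test_that("proteome generation: sizes, lengths, digestibility, determinism", {
  cfg <- simulation_config(seed = 1, n_proteins = 100,
                           protein_length_range = c(50, 500))
  p <- generate_proteome(cfg)
  expect_length(p, 100)
  expect_true(all(Biostrings::width(p) >= 50 & Biostrings::width(p) <= 500))
  # every sequence has a K or R so digestion is exercised
  expect_true(all(grepl("[KR]", as.character(p))))
  # only the 20 standard amino acids
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", as.character(p))))

  # empty collection
  expect_length(generate_proteome(simulation_config(n_proteins = 0)), 0)

  # identical seed, byte-identical FASTA
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(generate_proteome(cfg), f1)
  Biostrings::writeXStringSet(generate_proteome(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("every generator is deterministic under the seed and differs across seeds", {
  c1 <- simulation_config(seed = 4, n_proteins = 50, n_genes = 100,
                          n_background_promoters = 30, n_query_promoters = 10)
  c2 <- simulation_config(seed = 5, n_proteins = 50, n_genes = 100,
                          n_background_promoters = 30, n_query_promoters = 10)
  expect_identical(simulate_runs(generate_proteome(c1), c1),
                   simulate_runs(generate_proteome(c1), c1))
  expect_identical(generate_expression(c1), generate_expression(c1))
  expect_identical(generate_promoters(c1), generate_promoters(c1))
  expect_false(identical(as.character(generate_proteome(c1)),
                         as.character(generate_proteome(c2))))
})

test_that("run simulation: overlap structure, fold null, saturation limit", {
  cfg <- simulation_config(seed = 2, n_proteins = 1000)
  proteome <- generate_proteome(cfg)
  runs <- simulate_runs(proteome, cfg)
  expect_length(runs$reports, cfg$n_runs_wt + cfg$n_runs_mut)

  # replicate runs overlap only partially: not every protein is in all
  # wild-type runs, and some proteins are seen exactly once
  part <- overlap_partition(runs$reports[1:4], fdr_threshold = 101)
  expect_lt(part$count[4] / sum(part$count), 1)
  expect_gt(part$count[1], 0)

  # null effect: fold 1 makes the genotype latents identical
  cfg0 <- simulation_config(seed = 2, n_proteins = 200, substrate_fold = 1)
  runs0 <- simulate_runs(generate_proteome(cfg0), cfg0)
  expect_equal(runs0$latent$abundance_wt, runs0$latent$abundance_mut)

  # saturation limit: detection probability 1 puts every protein in every run
  cfgS <- simulation_config(seed = 2, n_proteins = 150,
                            detection_saturation = Inf)
  runsS <- simulate_runs(generate_proteome(cfgS), cfgS)
  for (r in runsS$reports) expect_equal(nrow(r), 150L)

  # planted truth is traceable and matches the latent flags
  expect_setequal(runs$truth,
                  runs$latent$protein_id[runs$latent$is_substrate])
  # substrate latents are exactly fold x wild type
  expect_equal(runs$latent$abundance_mut[runs$latent$is_substrate],
               runs$latent$abundance_wt[runs$latent$is_substrate] *
                 cfg$substrate_fold)

  # the reduced-input mutant test run is flagged out of quantification
  expect_false(attr(runs$reports[["mut_5"]], "include_in_quant"))
  expect_true(attr(runs$reports[["mut_1"]], "include_in_quant"))
})

test_that("simulated local FDR exercises the 1% filter predictably", {
  cfg <- simulation_config(seed = 13, n_proteins = 800)
  runs <- simulate_runs(generate_proteome(cfg), cfg)
  fdr <- unlist(lapply(runs$reports, `[[`, "local_fdr_pct"))
  expect_true(all(fdr >= 0 & fdr <= cfg$fdr_max))
  # the confident component puts ~90% of identifications under 1%
  expect_equal(mean(fdr < 1), cfg$fdr_conf_weight, tolerance = 0.05)
})

test_that("expression generation: noiseless null and planted folds are exact", {
  cfg0 <- simulation_config(seed = 3, n_genes = 100, expr_noise_sd = 0,
                            planted_de_fraction = 0, no_probe_fraction = 0)
  ex0 <- generate_expression(cfg0)
  wt_mean <- rowMeans(ex0$matrix[, ex0$groups == "wild_type", drop = FALSE])
  mut_mean <- rowMeans(ex0$matrix[, ex0$groups == "mutant", drop = FALSE])
  expect_equal(wt_mean, mut_mean)

  cfg2 <- simulation_config(seed = 3, n_genes = 100, expr_noise_sd = 0,
                            de_fold = 2, planted_de_fraction = 0.1,
                            no_probe_fraction = 0)
  ex2 <- generate_expression(cfg2)
  wt2 <- rowMeans(ex2$matrix[, ex2$groups == "wild_type", drop = FALSE])
  mut2 <- rowMeans(ex2$matrix[, ex2$groups == "mutant", drop = FALSE])
  fold <- mut2 / wt2
  expect_equal(unname(fold[ex2$de_truth]), rep(2, length(ex2$de_truth)))
  expect_equal(unname(fold[setdiff(names(fold), ex2$de_truth)]),
               rep(1, 100 - length(ex2$de_truth)))

  # the no-probe subset is withheld from the matrix but traceable
  cfg3 <- simulation_config(seed = 3, n_genes = 200, no_probe_fraction = 0.1)
  ex3 <- generate_expression(cfg3)
  expect_length(ex3$no_probe_genes, 20L)
  expect_false(any(ex3$no_probe_genes %in% rownames(ex3$matrix)))
  expect_equal(nrow(ex3$matrix), 180L)
})

test_that("DE caller recovers planted 4-fold genes with high power", {
  cfg <- simulation_config(seed = 23, n_genes = 2000,
                           planted_de_fraction = 0.05, de_fold = 4)
  ex <- generate_expression(cfg)
  de <- differential_expression(ex$matrix, ex$groups)
  planted_probed <- intersect(ex$de_truth, rownames(ex$matrix))
  recall <- mean(de$status[match(planted_probed, de$gene_id)] == "up")
  expect_gte(recall, 0.9)
})

test_that("promoter generation: null, saturation, and planted truth", {
  cfg0 <- simulation_config(seed = 4, planted_motif_rate = 0,
                            n_query_promoters = 200,
                            n_background_promoters = 200)
  pr0 <- generate_promoters(cfg0)
  q_with <- count_motif(pr0$query, cfg0$planted_motif)[["promoters_with"]]
  b_with <- count_motif(pr0$background, cfg0$planted_motif)[["promoters_with"]]
  # no planting: containment rates statistically indistinguishable
  expect_gt(prop.test(c(q_with, b_with), c(200, 200))$p.value, 0.01)
  expect_false(any(pr0$truth))

  cfg1 <- simulation_config(seed = 4, planted_motif_rate = 1,
                            n_query_promoters = 50,
                            n_background_promoters = 10)
  pr1 <- generate_promoters(cfg1)
  hits <- Biostrings::vcountPattern(cfg1$planted_motif, pr1$query)
  expect_true(all(hits >= 1))
  expect_true(all(pr1$truth))
  expect_true(all(Biostrings::width(pr1$query) == cfg1$promoter_length))
})
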