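#' Run the full substrate screen end to end
#'
#' Orchestrates the whole pipeline on in-memory inputs: theoretical
#' digestion, per-run spectral-counting normalization, replicate merging
#' under the local-FDR filter, overlap partitioning, pooled wild-type
#' construction, mutant-only / mutant-higher classification, differential
#' expression, the transcript-level exclusion filter and (optionally)
#' promoter-motif and GO enrichment of the candidate gene set.
#'
#' @param proteome Protein sequences ([Biostrings::AAStringSet] or named
#'   character vector) covering every detected protein.
#' @param reports List of run-report data frames with `genotype` and
#'   `include_in_quant` attributes (see [simulate_runs()],
#'   [read_run_report()]).
#' @param expression List with `matrix`, `groups`, `probe_map` as returned
#'   by [generate_expression()] (or built from files).
#' @param previous_wt Optional list of previously published wild-type
#'   protein id vectors for the pooled reference.
#' @param annotations Optional gene/term annotation data frame for GO
#'   enrichment of candidate genes (background = probed genes).
#' @param promoters Optional list with `query` and `background`
#'   [Biostrings::DNAStringSet]s for hexamer enrichment.
#' @param fdr_threshold Local FDR cutoff in percent (default 1, strict <).
#' @param higher_fold Mutant/wild-type abundance cutoff (default 1.5,
#'   inclusive).
#' @param de_fold Expression fold-change cutoff (default 2, inclusive).
#' @param alpha Significance level for the t-test and Fisher test.
#' @param motif_top Number of top motifs to report (default 5).
#' @param zero_impute,log2_input,var_equal,both_strands,tail Convention
#'   switches forwarded to the stage functions.
#' @param id_level Identifier level for cross-dataset comparisons.
#' @return List of class `screen_summary`; see the elements documented in
#'   the methods vignette: per-run detection counts, merged proteomes and
#'   partitions, pooled wild type, the candidate table and per-class
#'   summary, DE results, and any enrichment tables.
#' @export
run_screen <- function(proteome, reports, expression,
                       previous_wt = list(), annotations = NULL,
                       promoters = NULL,
                       fdr_threshold = 1, higher_fold = 1.5, de_fold = 2,
                       alpha = 0.05, motif_top = 5L, zero_impute = FALSE,
                       log2_input = FALSE, var_equal = TRUE,
                       both_strands = FALSE, tail = FALSE,
                       id_level = "isoform") {
  stopifnot(length(reports) >= 1L)
  genotypes <- vapply(reports, function(r) attr(r, "genotype") %||% NA_character_,
                      character(1))
  if (anyNA(genotypes) || !all(genotypes %in% c("wild_type", "mutant"))) {
    stop("every report needs a genotype attribute (wild_type/mutant)", call. = FALSE)
  }
  wt_reports <- reports[genotypes == "wild_type"]
  mut_reports <- reports[genotypes == "mutant"]
  if (length(wt_reports) == 0L) stop("no wild-type runs supplied", call. = FALSE)
  if (length(mut_reports) == 0L) stop("no mutant runs supplied", call. = FALSE)

  # stage: digest
  digest <- theoretical_counts(proteome)

  # stage: per-run FDR filter + spectral-counting normalization
  filter_fdr <- function(r) {
    keep <- r$local_fdr_pct < fdr_threshold
    out <- r[keep, , drop = FALSE]
    for (a in c("run_id", "genotype", "include_in_quant")) {
      attr(out, a) <- attr(r, a)
    }
    out
  }
  wt_f <- lapply(wt_reports, filter_fdr)
  mut_f <- lapply(mut_reports, filter_fdr)
  wt_tabs <- lapply(wt_f, normalize_run, digest = digest)
  mut_tabs <- lapply(mut_f, normalize_run, digest = digest)
  mean_wt <- average_abundance(wt_tabs, zero_impute = zero_impute)
  mean_mut <- average_abundance(mut_tabs, zero_impute = zero_impute)

  # stage: set comparisons
  wt_prot <- merge_runs(wt_reports, fdr_threshold, label = "wild_type",
                        id_level = id_level)
  mut_prot <- merge_runs(mut_reports, fdr_threshold, label = "mutant",
                         id_level = id_level)
  quant_mut_reports <- mut_reports[vapply(mut_reports, function(r)
    isTRUE(attr(r, "include_in_quant") %||% TRUE), logical(1))]
  partitions <- list(
    wild_type = if (length(wt_reports) >= 2L)
      overlap_partition(wt_reports, fdr_threshold, id_level = id_level),
    mutant = if (length(quant_mut_reports) >= 2L)
      overlap_partition(quant_mut_reports, fdr_threshold, id_level = id_level)
  )
  pooled <- pool_wildtype(wt_prot, previous_wt, id_level = id_level)
  only_ids <- mutant_only(mut_prot, pooled)

  # stage: mutant-higher on proteins quantified in both genotypes
  both <- merge(mean_mut, mean_wt, by = "protein_id",
                suffixes = c("_mut", "_wt"))
  both <- both[!(normalize_ids(both$protein_id, id_level) %in%
                   normalize_ids(only_ids, id_level)), , drop = FALSE]
  higher_ids <- sort(both$protein_id[
    classify_higher(both$mean_abundance_mut, both$mean_abundance_wt,
                    higher_fold)])

  # stage: differential expression + transcript filter
  de <- differential_expression(expression$matrix, expression$groups,
                                fold_cutoff = de_fold, alpha = alpha,
                                log2_input = log2_input,
                                var_equal = var_equal)
  classes <- data.frame(
    protein_id = c(only_ids, higher_ids),
    class = rep(c("mutant_only", "mutant_higher"),
                c(length(only_ids), length(higher_ids))),
    stringsAsFactors = FALSE
  )
  statuses <- transcript_status(classes$protein_id, de, expression$probe_map)
  accounting <- candidate_accounting(classes, statuses)
  candidates <- accounting$table$protein_id[accounting$table$protein_level_candidate]

  # stage: enrichment (optional)
  motifs <- if (!is.null(promoters)) {
    rank_motifs(promoters$query, promoters$background, top = motif_top,
                both_strands = both_strands, tail = tail)
  }
  go <- if (!is.null(annotations)) {
    fisher_go(annotations,
              intersect(strip_isoform(candidates), expression$probe_map),
              expression$probe_map, alpha = alpha)
  }

  structure(list(
    n_detected_per_run = vapply(reports, function(r)
      sum(r$local_fdr_pct < fdr_threshold), integer(1)),
    digest_total = digest$total,
    wild_type_proteome = wt_prot,
    mutant_proteome = mut_prot,
    partitions = partitions,
    pooled_wt = pooled,
    mean_abundance = list(wild_type = mean_wt, mutant = mean_mut),
    mutant_only_ids = only_ids,
    mutant_higher_ids = higher_ids,
    de = de,
    accounting = accounting,
    candidates = sort(candidates),
    motifs = motifs,
    go = go,
    thresholds = list(fdr_threshold = fdr_threshold,
                      higher_fold = higher_fold, de_fold = de_fold,
                      alpha = alpha)
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Substrate screen summary\n")
  cat(sprintf("  wild-type proteome: %d proteins; mutant: %d\n",
              length(x$wild_type_proteome$members),
              length(x$mutant_proteome$members)))
  cat(sprintf("  pooled wild type: %d (own contribution %.1f %%)\n",
              x$pooled_wt$pooled_size, x$pooled_wt$contribution_pct))
  cat(sprintf("  mutant-only: %d, mutant-higher: %d\n",
              length(x$mutant_only_ids), length(x$mutant_higher_ids)))
  cat(sprintf("  protein-level candidates after transcript filter: %d\n",
              length(x$candidates)))
  invisible(x)
}

#' Formatted percentage lines for a screen summary
#'
#' Renders the headline count/total pairs of a screen as
#' `"count/total (pct %)"` lines with one-decimal half-up rounding, the
#' convention used for reporting replicate-overlap and pooled-contribution
#' fractions.
#'
#' @param summary A `screen_summary` from [run_screen()].
#' @return Character vector of formatted lines.
#' @seealso [format_pct()] for a single pair.
#' @export
report_fractions <- function(summary) {
  lines <- character(0)
  for (g in names(summary$partitions)) {
    part <- summary$partitions[[g]]
    if (is.null(part)) next
    total <- sum(part$count)
    lines <- c(lines, sprintf("%s: %d of %d proteins (%s) detected in %d run(s)",
                              g, part$count, total,
                              format_pct(part$count, total), part$n_runs))
  }
  lines <- c(lines, sprintf(
    "own wild-type contribution to pooled: %d/%d (%s)",
    summary$pooled_wt$own_size, summary$pooled_wt$pooled_size,
    format_pct(summary$pooled_wt$own_size, summary$pooled_wt$pooled_size)))
  lines
}

#' Format a count/total pair as a percentage
#'
#' @param count,total Numeric scalars or vectors.
#' @return Character, e.g. `"27.5 %"` for 884/3220 (one decimal, half-up).
#' @export
format_pct <- function(count, total) {
  sprintf("%.1f %%", round_half_up(100 * count / total, 1L))
}

#' Write the tabular outputs of a screen to a directory
#'
#' Writes merged-proteome id lists, overlap partitions, genotype-mean
#' abundances, the DE table, candidate table and per-class summary, motif
#' and GO tables (when present) as TSV, and the headline counts as JSON.
#'
#' @param summary A `screen_summary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_outputs <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  write_id_list(summary$wild_type_proteome$members,
                file.path(dir, "proteome_wild_type.txt"))
  write_id_list(summary$mutant_proteome$members,
                file.path(dir, "proteome_mutant.txt"))
  write_id_list(summary$mutant_only_ids, file.path(dir, "mutant_only.txt"))
  write_id_list(summary$mutant_higher_ids, file.path(dir, "mutant_higher.txt"))
  write_id_list(summary$candidates, file.path(dir, "candidates.txt"))
  for (g in names(summary$partitions)) {
    if (!is.null(summary$partitions[[g]]))
      w(summary$partitions[[g]], sprintf("overlap_partition_%s.tsv", g))
  }
  w(summary$mean_abundance$wild_type, "mean_abundance_wild_type.tsv")
  w(summary$mean_abundance$mutant, "mean_abundance_mutant.tsv")
  w(summary$de, "differential_expression.tsv")
  w(summary$accounting$table, "candidate_table.tsv")
  w(summary$accounting$summary, "candidate_summary.tsv")
  if (!is.null(summary$motifs)) w(summary$motifs, "top_motifs.tsv")
  if (!is.null(summary$go)) w(summary$go, "go_enrichment.tsv")
  headline <- list(
    n_detected_per_run = as.list(summary$n_detected_per_run),
    wild_type_proteome = length(summary$wild_type_proteome$members),
    mutant_proteome = length(summary$mutant_proteome$members),
    pooled_wt = summary$pooled_wt$pooled_size,
    contribution_pct = summary$pooled_wt$contribution_pct,
    mutant_only = length(summary$mutant_only_ids),
    mutant_higher = length(summary$mutant_higher_ids),
    candidates = length(summary$candidates),
    thresholds = summary$thresholds
  )
  jsonlite::write_json(headline, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a complete dataset and run the screen on it
#'
#' Convenience wrapper: generates proteome, run reports, expression matrix
#' and promoter sets from one [simulation_config()] and feeds them to
#' [run_screen()]. Planted differentially expressed genes are drawn from
#' genes not encoding planted substrates, so the substrate truth stays
#' clean for recovery checks.
#'
#' @param config A [simulation_config()].
#' @param with_promoters Also generate promoter sets and rank motifs
#'   (default `TRUE`); `FALSE` runs the proteomic/transcriptomic stages
#'   only.
#' @param ... Threshold/convention arguments forwarded to [run_screen()].
#' @return List: `summary` (the `screen_summary`), `truth` (list with
#'   planted `substrates`, `de_genes`, `motif_planted`), and the generated
#'   `inputs`.
#' @export
simulate_and_screen <- function(config, with_promoters = TRUE, ...) {
  proteome <- generate_proteome(config)
  runs <- simulate_runs(proteome, config)
  substrate_genes <- strip_isoform(runs$truth)
  all_genes <- agi_gene_id(seq_len(config$n_genes))
  de_pool <- setdiff(all_genes, substrate_genes)
  de_genes <- withr::with_seed(stream_seed(config, 5L),
    sort(sample(de_pool, round(config$planted_de_fraction * config$n_genes))))
  expr <- generate_expression(config, de_genes = de_genes)
  prom <- if (with_promoters) generate_promoters(config)
  summary <- run_screen(proteome, runs$reports, expr,
                        promoters = prom, ...)
  list(summary = summary,
       truth = list(substrates = runs$truth, de_genes = expr$de_truth,
                    motif_planted = prom$truth %||% NULL),
       inputs = list(proteome = proteome, runs = runs, expression = expr,
                     promoters = prom))
}
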