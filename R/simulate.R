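#' Configuration for the synthetic screen data generators
#'
#' One configuration object drives every generator, and an identical
#' configuration yields bit-identical outputs (each generator derives its
#' own RNG stream from `seed`, so generators can be called in any order).
#'
#' Defaults mirror the study design the pipeline targets: 4 wild-type and
#' 5 mutant MS runs with the fifth mutant run a reduced-input test run
#' (kept in set unions, excluded from quantification), and 4 wild-type vs
#' 3 mutant expression replicates.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param protein_length_range Length-2 integer vector, amino acids.
#' @param n_runs_wt,n_runs_mut MS runs per genotype (defaults 4 and 5).
#' @param planted_substrate_fraction Fraction of proteins planted as
#'   ligase substrates (elevated in the mutant).
#' @param substrate_fold Mutant/wild-type latent abundance ratio for
#'   planted substrates (>= 1.5; default 4, a strong accumulation typical
#'   of a degradation mutant).
#' @param detection_saturation Saturation coefficient c of the detection
#'   model p = cA/(1 + cA); `Inf` forces detection of every protein.
#' @param count_rate Expected spectra per unit (abundance x peptide);
#'   spectral counts are Poisson with this rate unless
#'   `poisson_counts = FALSE` (then rounded expectations, for noiseless
#'   runs).
#' @param poisson_counts Draw spectral counts from a Poisson (default);
#'   `FALSE` uses rounded expectations (noiseless counts).
#' @param fdr_max Upper bound (percent) of the simulated local FDR mixture;
#'   0 makes every identification perfectly confident.
#' @param fdr_conf_weight Probability that an identification draws its
#'   local FDR from the confident component U(0, 1)%; the rest draw from
#'   U(1, fdr_max)% and are removed by the standard <1% filter.
#' @param mutant_test_run Make the last mutant run reduced-input
#'   (`test_run_input_fraction` of material) and flag it
#'   `include_in_quant = FALSE` (default `TRUE` when `n_runs_mut >= 2`).
#' @param test_run_input_fraction Input fraction for the test run.
#' @param n_genes Genes in the expression matrix (gene i encodes protein
#'   isoform i, so n_genes >= n_proteins covers the proteome).
#' @param n_expr_reps_wt,n_expr_reps_mut Expression replicates (4 and 3).
#' @param planted_de_fraction Fraction of genes planted as differentially
#'   expressed.
#' @param de_fold Planted expression fold change (>= 2).
#' @param expr_noise_sd Additive Gaussian noise SD on the linear expression
#'   scale (baselines are drawn in \[0.5, 2\], so 0.2 is ~10-40% CV).
#' @param no_probe_fraction Fraction of genes absent from the probe map.
#' @param promoter_length Promoter length in bases (500 or 1000).
#' @param planted_motif Hexamer planted into query promoters.
#' @param planted_motif_rate Per-promoter probability of one insertion.
#' @param n_query_promoters,n_background_promoters Promoter set sizes.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 1000L,
                              protein_length_range = c(50L, 500L),
                              n_runs_wt = 4L,
                              n_runs_mut = 5L,
                              planted_substrate_fraction = 0.05,
                              substrate_fold = 4,
                              detection_saturation = 2,
                              count_rate = 1,
                              poisson_counts = TRUE,
                              fdr_max = 5,
                              fdr_conf_weight = 0.9,
                              mutant_test_run = n_runs_mut >= 2L,
                              test_run_input_fraction = 0.2,
                              n_genes = 2000L,
                              n_expr_reps_wt = 4L,
                              n_expr_reps_mut = 3L,
                              planted_de_fraction = 0.05,
                              de_fold = 2,
                              expr_noise_sd = 0.2,
                              no_probe_fraction = 0.02,
                              promoter_length = 500L,
                              planted_motif = "CACGTG",
                              planted_motif_rate = 0.3,
                              n_query_promoters = 42L,
                              n_background_promoters = 2000L) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              protein_length_range = as.integer(protein_length_range),
              n_runs_wt = as.integer(n_runs_wt),
              n_runs_mut = as.integer(n_runs_mut),
              planted_substrate_fraction = planted_substrate_fraction,
              substrate_fold = substrate_fold,
              detection_saturation = detection_saturation,
              count_rate = count_rate, poisson_counts = poisson_counts,
              fdr_max = fdr_max, fdr_conf_weight = fdr_conf_weight,
              mutant_test_run = mutant_test_run,
              test_run_input_fraction = test_run_input_fraction,
              n_genes = as.integer(n_genes),
              n_expr_reps_wt = as.integer(n_expr_reps_wt),
              n_expr_reps_mut = as.integer(n_expr_reps_mut),
              planted_de_fraction = planted_de_fraction, de_fold = de_fold,
              expr_noise_sd = expr_noise_sd,
              no_probe_fraction = no_probe_fraction,
              promoter_length = as.integer(promoter_length),
              planted_motif = toupper(planted_motif),
              planted_motif_rate = planted_motif_rate,
              n_query_promoters = as.integer(n_query_promoters),
              n_background_promoters = as.integer(n_background_promoters))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  props <- c("planted_substrate_fraction", "planted_de_fraction",
             "planted_motif_rate", "no_probe_fraction", "fdr_conf_weight",
             "test_run_input_fraction")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("configuration error: %s must lie in [0, 1]", p), call. = FALSE)
    }
  }
  if (cfg$substrate_fold < 1 || cfg$de_fold < 1) {
    stop("configuration error: fold multipliers must be >= 1", call. = FALSE)
  }
  if (length(cfg$protein_length_range) != 2L ||
      any(cfg$protein_length_range < 2L) ||
      cfg$protein_length_range[1] > cfg$protein_length_range[2]) {
    stop("configuration error: invalid protein length range", call. = FALSE)
  }
  if (cfg$promoter_length < nchar(cfg$planted_motif)) {
    stop("configuration error: promoter shorter than planted motif", call. = FALSE)
  }
  if (grepl("[^ACGT]", cfg$planted_motif)) {
    stop("configuration error: planted motif must be over ACGT", call. = FALSE)
  }
  if (cfg$expr_noise_sd < 0 || cfg$fdr_max < 0 || cfg$count_rate <= 0 ||
      cfg$detection_saturation <= 0) {
    stop("configuration error: negative noise/rate parameter", call. = FALSE)
  }
  invisible(cfg)
}

# independent, order-insensitive RNG stream per generator
stream_seed <- function(cfg, offset) {
  as.integer((as.double(cfg$seed) * 7919 + offset * 104729) %% 2147483647)
}

agi_gene_id <- function(i) {
  sprintf("AT%dG%05d", (i - 1L) %% 5L + 1L, ((i - 1L) %/% 5L + 1L) * 10L)
}

#' Generate a synthetic proteome
#'
#' Random protein sequences over the 20 standard amino acids with lengths
#' uniform in `protein_length_range`. Every sequence is guaranteed at least
#' one K or R so tryptic digestion is exercised. Identifiers are
#' AGI-isoform style (`AT1G00010.1`); protein i encodes gene i of the
#' expression module.
#'
#' @param config A [simulation_config()].
#' @return [Biostrings::AAStringSet], one record per protein.
#' @export
generate_proteome <- function(config) {
  withr::with_seed(stream_seed(config, 1L), {
    n <- config$n_proteins
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    lens <- if (n > 0) sample(seq(config$protein_length_range[1],
                                  config$protein_length_range[2]),
                              n, replace = TRUE) else integer(0)
    seqs <- vapply(lens, function(L) {
      s <- sample(aa, L, replace = TRUE)
      if (!any(s %in% c("K", "R"))) {
        s[sample.int(L, 1L)] <- sample(c("K", "R"), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- if (n > 0) paste0(agi_gene_id(seq_len(n)), ".1") else character(0)
    out
  })
}

#' Simulate replicate MS run reports for both genotypes
#'
#' Each protein gets a latent wild-type abundance A ~ lognormal(0, 1); a
#' planted fraction of proteins (the "substrates") have mutant abundance
#' `substrate_fold` x A. Per run, detection is Bernoulli with saturating
#' probability p = cA/(1 + cA), so replicate runs overlap only partially;
#' spectral counts for detected proteins are Poisson with mean
#' `count_rate` x A x t (t = theoretical peptide count), floored at 1.
#' Simulated local FDRs are a confident/marginal mixture (see
#' [simulation_config()]) so the standard <1% filter removes a predictable
#' fraction of identifications. The optional reduced-input mutant test run
#' scales A by `test_run_input_fraction` and is flagged
#' `include_in_quant = FALSE`.
#'
#' @param proteome [Biostrings::AAStringSet] from [generate_proteome()].
#' @param config A [simulation_config()].
#' @param digest Optional precomputed [theoretical_counts()] of `proteome`.
#' @return List with `reports` (list of run-report data frames
#'   `protein_id`, `spectra`, `local_fdr_pct`, with attributes `run_id`,
#'   `genotype`, `include_in_quant`), `truth` (planted substrate ids) and
#'   `latent` (data frame of latent abundances per genotype).
#' @export
simulate_runs <- function(proteome, config, digest = NULL) {
  if (length(proteome) == 0L) stop("empty proteome", call. = FALSE)
  if (is.null(digest)) digest <- theoretical_counts(proteome)
  ids <- digest$counts$protein_id
  t_k <- digest$counts$n_peptides
  withr::with_seed(stream_seed(config, 2L), {
    n <- length(ids)
    A_wt <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    n_sub <- round(config$planted_substrate_fraction * n)
    sub_idx <- sort(sample.int(n, n_sub))
    A_mut <- A_wt
    A_mut[sub_idx] <- A_mut[sub_idx] * config$substrate_fold

    one_run <- function(run_id, genotype, A, input_fraction = 1) {
      A <- A * input_fraction
      p_det <- if (is.infinite(config$detection_saturation)) rep(1, n) else {
        cA <- config$detection_saturation * A
        cA / (1 + cA)
      }
      det <- stats::runif(n) < p_det
      lambda <- config$count_rate * A * pmax(t_k, 1L)
      spectra <- if (config$poisson_counts) {
        pmax(stats::rpois(n, lambda), 1L)
      } else {
        pmax(round(lambda), 1L)
      }
      fdr <- if (config$fdr_max <= 0) rep(0, n) else {
        conf <- stats::runif(n) < config$fdr_conf_weight
        ifelse(conf, stats::runif(n, 0, min(1, config$fdr_max)),
               stats::runif(n, min(1, config$fdr_max), config$fdr_max))
      }
      rep_df <- data.frame(protein_id = ids[det],
                           spectra = as.integer(spectra[det]),
                           local_fdr_pct = fdr[det],
                           stringsAsFactors = FALSE)
      attr(rep_df, "run_id") <- run_id
      attr(rep_df, "genotype") <- genotype
      attr(rep_df, "include_in_quant") <- TRUE
      rep_df
    }

    reports <- list()
    for (i in seq_len(config$n_runs_wt)) {
      reports[[paste0("wt_", i)]] <- one_run(paste0("wt_", i), "wild_type", A_wt)
    }
    for (i in seq_len(config$n_runs_mut)) {
      is_test <- config$mutant_test_run && i == config$n_runs_mut
      r <- one_run(paste0("mut_", i), "mutant", A_mut,
                   input_fraction = if (is_test) config$test_run_input_fraction else 1)
      if (is_test) attr(r, "include_in_quant") <- FALSE
      reports[[paste0("mut_", i)]] <- r
    }
    list(reports = reports,
         truth = ids[sub_idx],
         latent = data.frame(protein_id = ids, abundance_wt = A_wt,
                             abundance_mut = A_mut,
                             is_substrate = seq_len(n) %in% sub_idx,
                             stringsAsFactors = FALSE))
  })
}

#' Generate a normalized expression matrix with planted DE genes
#'
#' Linear-scale expression values emulating a normalized (RMA-style,
#' anti-logged) microarray matrix. Each gene draws a baseline in
#' \[0.5, 2\]; planted genes have mutant mean = `de_fold` x baseline,
#' others 1 x; values get additive Gaussian noise with SD `expr_noise_sd`
#' (floored at 0.01 to stay positive). A `no_probe_fraction` of genes is
#' withheld from the matrix, emulating genes without probes on the array.
#'
#' @param config A [simulation_config()].
#' @param de_genes Optional character vector of gene ids to plant as
#'   differentially expressed; by default a `planted_de_fraction` sample.
#' @return List: `matrix` (probed genes x samples), `groups` (column group
#'   labels), `probe_map` (probed gene ids), `de_truth` (planted DE gene
#'   ids), `no_probe_genes`.
#' @export
generate_expression <- function(config, de_genes = NULL) {
  withr::with_seed(stream_seed(config, 3L), {
    genes <- agi_gene_id(seq_len(config$n_genes))
    if (is.null(de_genes)) {
      de_genes <- sort(sample(genes, round(config$planted_de_fraction *
                                             config$n_genes)))
    } else {
      stopifnot(all(de_genes %in% genes))
      de_genes <- sort(unique(de_genes))
    }
    n_np <- round(config$no_probe_fraction * config$n_genes)
    no_probe <- sort(sample(genes, n_np))
    probed <- setdiff(genes, no_probe)

    n_wt <- config$n_expr_reps_wt
    n_mut <- config$n_expr_reps_mut
    groups <- c(rep("wild_type", n_wt), rep("mutant", n_mut))
    base <- stats::runif(config$n_genes, 0.5, 2)
    mu <- cbind(matrix(base, config$n_genes, n_wt),
                matrix(base * ifelse(genes %in% de_genes, config$de_fold, 1),
                       config$n_genes, n_mut))
    vals <- mu + matrix(stats::rnorm(length(mu), 0, config$expr_noise_sd),
                        nrow = config$n_genes)
    vals <- pmax(vals, 0.01)
    rownames(vals) <- genes
    colnames(vals) <- c(paste0("wt_", seq_len(n_wt)),
                        paste0("mut_", seq_len(n_mut)))
    list(matrix = vals[probed, , drop = FALSE],
         groups = groups,
         probe_map = probed,
         de_truth = de_genes,
         no_probe_genes = no_probe)
  })
}

#' Generate query and background promoter sets with a planted motif
#'
#' Background promoters are i.i.d. uniform over ACGT. Query promoters are
#' likewise uniform, but each receives (with probability
#' `planted_motif_rate`) one insertion of the planted hexamer at a uniform
#' position, overwriting the bases there.
#'
#' @param config A [simulation_config()].
#' @return List: `query` and `background` ([Biostrings::DNAStringSet]s) and
#'   `truth` (logical: which query promoters received an insertion).
#' @export
generate_promoters <- function(config) {
  withr::with_seed(stream_seed(config, 4L), {
    L <- config$promoter_length
    bases <- c("A", "C", "G", "T")
    rand_seqs <- function(n) {
      if (n == 0L) return(character(0))
      m <- matrix(sample(bases, n * L, replace = TRUE), nrow = n)
      apply(m, 1L, paste, collapse = "")
    }
    bg <- rand_seqs(config$n_background_promoters)
    qy <- rand_seqs(config$n_query_promoters)
    motif <- config$planted_motif
    w <- nchar(motif)
    planted <- stats::runif(config$n_query_promoters) < config$planted_motif_rate
    for (i in which(planted)) {
      pos <- sample.int(L - w + 1L, 1L)
      substr(qy[i], pos, pos + w - 1L) <- motif
    }
    query <- Biostrings::DNAStringSet(qy)
    background <- Biostrings::DNAStringSet(bg)
    if (length(query)) names(query) <- paste0("query_", seq_along(query))
    if (length(background)) names(background) <- paste0("bg_", seq_along(background))
    list(query = query, background = background, truth = planted)
  })
}
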