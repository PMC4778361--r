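#' Spectral-counting normalization of one MS run
#'
#' Converts raw spectral counts into normalized relative abundances. For
#' protein K with measured spectra s_K and theoretical tryptic peptide count
#' t_K, the abundance is
#'
#'   A_K = (s_K / S) / (t_K / T)
#'
#' where S and T are the totals of s and t over the proteins detected in
#' this run. Both totals are per-run: the dataset is the single sample. A_K
#' is a dimensionless ratio; a protein whose spectra share equals its
#' theoretical-peptide share has A_K = 1.
#'
#' Proteins with t_K = 0 cannot be normalized; they are excluded from the
#' table and returned under `unquantifiable` (their spectra do not enter S,
#' and their peptide counts do not enter T, so the t-weighted mean of A_K
#' over the table is exactly 1).
#'
#' @param report Run report data frame with columns `protein_id`, `spectra`
#'   (positive integers) and optionally `local_fdr_pct`; typically one
#'   element of [simulate_runs()] output or [read_run_report()].
#' @param digest A `theoretical_digest` from [theoretical_counts()], or a
#'   data frame with columns `protein_id` and `n_peptides`. Every detected
#'   protein must have an entry.
#' @return Object of class `abundance_table`: list with `run_id`,
#'   `abundance` (data frame: `protein_id`, `spectra`, `n_peptides`,
#'   `abundance`), `unquantifiable` (ids with t = 0), and the totals `S`,
#'   `T`.
#' @examples
#' rep <- data.frame(protein_id = c("P1", "P2"), spectra = c(20, 20))
#' dig <- data.frame(protein_id = c("P1", "P2"), n_peptides = c(2, 6))
#' normalize_run(rep, dig)$abundance$abundance  # 2 and 2/3
#' @export
normalize_run <- function(report, digest) {
  stopifnot(is.data.frame(report),
            all(c("protein_id", "spectra") %in% names(report)))
  counts <- digest_counts(digest)
  idx <- match(report$protein_id, counts$protein_id)
  if (anyNA(idx)) {
    stop("detected proteins missing from digest: ",
         paste(utils::head(report$protein_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(report$spectra < 1)) {
    stop("detected proteins must have spectral count >= 1", call. = FALSE)
  }
  t_k <- counts$n_peptides[idx]
  quant <- t_k > 0L
  s_k <- report$spectra[quant]
  t_q <- t_k[quant]
  S <- sum(s_k)
  TT <- sum(t_q)
  if (S <= 0) stop("no quantifiable spectra in run", call. = FALSE)
  tab <- data.frame(
    protein_id = report$protein_id[quant],
    spectra = s_k,
    n_peptides = t_q,
    abundance = (s_k / S) / (t_q / TT),
    stringsAsFactors = FALSE
  )
  out <- structure(list(run_id = attr(report, "run_id") %||% NA_character_,
                        abundance = tab,
                        unquantifiable = report$protein_id[!quant],
                        S = S, T = TT),
                   class = "abundance_table")
  attr(out, "include_in_quant") <- attr(report, "include_in_quant") %||% TRUE
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table (run %s): %d proteins, S = %d spectra, T = %d peptides; %d unquantifiable\n",
              x$run_id, nrow(x$abundance), x$S, x$T, length(x$unquantifiable)))
  invisible(x)
}

#' Replicate-averaged protein abundance for one genotype
#'
#' Averages per-run normalized abundances across the runs of one genotype.
#' By default the mean is taken over the runs in which the protein was
#' detected; `zero_impute = TRUE` instead averages over all included runs,
#' counting 0 for runs lacking the protein. Runs flagged
#' `include_in_quant = FALSE` (e.g. a reduced-input test run) are excluded
#' entirely.
#'
#' @param tables List of `abundance_table`s (one genotype's runs).
#' @param include Logical vector, one per table, marking runs that enter
#'   quantification. Defaults to each table's report-level
#'   `include_in_quant` attribute if present, else all `TRUE`.
#' @param zero_impute Average over all included runs with 0 for non-detected
#'   runs, instead of detected-runs-only (the default convention).
#' @return Data frame: `protein_id`, `n_runs_detected`, `mean_abundance`.
#'   Proteins detected in no included run are absent.
#' @export
average_abundance <- function(tables, include = NULL, zero_impute = FALSE) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  if (is.null(include)) {
    include <- vapply(tables, function(x) attr(x, "include_in_quant") %||% TRUE,
                      logical(1))
  }
  stopifnot(length(include) == length(tables))
  tables <- tables[include]
  if (length(tables) == 0L) {
    return(data.frame(protein_id = character(0), n_runs_detected = integer(0),
                      mean_abundance = numeric(0), stringsAsFactors = FALSE))
  }
  long <- do.call(rbind, lapply(tables, function(x) {
    x$abundance[, c("protein_id", "abundance")]
  }))
  n_det <- tapply(long$abundance, long$protein_id, length)
  tot <- tapply(long$abundance, long$protein_id, sum)
  denom <- if (zero_impute) length(tables) else as.integer(n_det)
  out <- data.frame(
    protein_id = names(tot),
    n_runs_detected = as.integer(n_det),
    mean_abundance = as.numeric(tot) / denom,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}

#' Flag proteins with higher abundance in the mutant
#'
#' A protein detected in both genotypes is "mutant-higher" when its mean
#' normalized abundance in the mutant is at least `threshold` times the
#' wild-type mean (the boundary is inclusive). Proteins absent from the
#' wild type belong to the mutant-only class and must not be passed here.
#'
#' @param mean_mut,mean_wt Positive numeric vectors of replicate-averaged
#'   abundances (recycled as usual).
#' @param threshold Fold-change cutoff, default 1.5.
#' @return Logical vector: `mean_mut / mean_wt >= threshold`.
#' @export
classify_higher <- function(mean_mut, mean_wt, threshold = 1.5) {
  if (any(mean_mut <= 0) || any(mean_wt <= 0)) {
    stop("mean abundances must be positive; mutant-only proteins are classified upstream",
         call. = FALSE)
  }
  mean_mut / mean_wt >= threshold
}

digest_counts <- function(digest) {
  if (inherits(digest, "theoretical_digest")) return(digest$counts)
  stopifnot(is.data.frame(digest),
            all(c("protein_id", "n_peptides") %in% names(digest)))
  digest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
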