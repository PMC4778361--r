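#' Differential expression by fold change and Student's t-test
#'
#' Calls each gene up- or down-regulated in the mutant when both criteria
#' hold jointly: at least `fold_cutoff`-fold difference between the group
#' means and a two-sided two-sample t-test p-value below `alpha`. The test
#' is the classical equal-variance (pooled) t-test by default; Welch is
#' available. No multiple-testing correction is applied: the screen uses
#' raw p-values throughout.
#'
#' With `log2_input = FALSE` (default) the matrix is on a linear scale and
#' the fold change is the ratio of group means; with `log2_input = TRUE`
#' the fold change is `2^(mean difference)`. Fold boundaries are inclusive
#' (`>= fold_cutoff` up, `<= 1/fold_cutoff` down).
#'
#' Genes with a zero (or negative) wild-type mean on the linear scale have
#' no defined ratio: they are flagged `fold_undefined`, reported with
#' `fold = NA`, excluded from up/down, and a warning is emitted.
#'
#' @param matrix Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @param groups Character/factor vector over columns with levels
#'   `"wild_type"` and `"mutant"`; each group needs >= 2 samples.
#' @param fold_cutoff Fold-change cutoff (default 2).
#' @param alpha Significance level for the raw p-value (default 0.05).
#' @param log2_input Interpret values as log2-scale (default `FALSE`).
#' @param var_equal Pooled-variance t-test (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return Data frame of class `de_result`: `gene_id`, `mean_wt`,
#'   `mean_mut`, `fold` (mutant/wild-type), `t_stat`, `df`, `p_value`,
#'   `fold_undefined`, `status` in `up`/`down`/`unchanged`.
#' @export
differential_expression <- function(matrix, groups, fold_cutoff = 2,
                                    alpha = 0.05, log2_input = FALSE,
                                    var_equal = TRUE) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            length(groups) == ncol(matrix))
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("wild_type", "mutant"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  wt <- matrix[, groups == "wild_type", drop = FALSE]
  mut <- matrix[, groups == "mutant", drop = FALSE]
  if (ncol(wt) < 2L || ncol(mut) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(matrix)) stop("expression matrix contains missing values", call. = FALSE)

  n1 <- ncol(wt); n2 <- ncol(mut)
  m1 <- rowMeans(wt); m2 <- rowMeans(mut)
  v1 <- apply(wt, 1L, stats::var)
  v2 <- apply(mut, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m2 - m1) / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # identical groups: se = 0 and t undefined; no evidence of change
  degenerate <- is.nan(tt)
  tt[degenerate] <- 0
  p[degenerate] <- 1

  if (log2_input) {
    fold <- 2^(m2 - m1)
    undef <- rep(FALSE, length(fold))
  } else {
    undef <- m1 <= 0
    fold <- ifelse(undef, NA_real_, m2 / m1)
    if (any(undef)) {
      warning(sum(undef), " gene(s) with non-positive wild-type mean: fold undefined, excluded from up/down",
              call. = FALSE)
    }
  }
  status <- rep("unchanged", length(fold))
  sig <- !undef & p < alpha
  status[sig & fold >= fold_cutoff] <- "up"
  status[sig & fold <= 1 / fold_cutoff] <- "down"
  out <- data.frame(
    gene_id = rownames(matrix),
    mean_wt = m1, mean_mut = m2, fold = fold,
    t_stat = tt, df = df, p_value = p,
    fold_undefined = undef, status = status,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("de_result", class(out))
  out
}

#' Transcript-level status of candidate proteins
#'
#' Maps each protein to its gene (AGI isoform suffix stripped; the
#' expression array is gene-level) and looks up the gene's differential-
#' expression status. A gene absent from the probe map — or present but
#' without a row in the DE table, i.e. never measured — is `no_probe`.
#'
#' @param protein_ids Character vector of protein (isoform) identifiers.
#' @param de A `de_result` from [differential_expression()].
#' @param probe_map Character vector of gene ids represented on the array.
#' @return Named character vector (names = `protein_ids`) with values in
#'   `up`, `down`, `unchanged`, `no_probe`.
#' @export
transcript_status <- function(protein_ids, de, probe_map) {
  genes <- strip_isoform(protein_ids)
  status <- de$status[match(genes, strip_isoform(de$gene_id))]
  status[is.na(status) | !(genes %in% strip_isoform(probe_map))] <- "no_probe"
  stats::setNames(status, protein_ids)
}

#' Candidate accounting: the transcript-level exclusion filter
#'
#' Combines the proteome-level classes (mutant-only, mutant-higher) with
#' transcript statuses. A protein whose transcript is `unchanged` is a
#' protein-level candidate: its accumulation in the mutant cannot be
#' explained by increased transcription, implicating regulation by
#' degradation. Proteins whose genes lack probes are counted separately
#' (they may still be candidates but cannot be filtered), and proteins with
#' up/down transcripts are excluded.
#'
#' @param classes Data frame with columns `protein_id` and `class`
#'   (`"mutant_only"` or `"mutant_higher"`).
#' @param statuses Named character vector from [transcript_status()]
#'   covering every classified protein.
#' @return List with `table` (per-protein: `protein_id`, `class`,
#'   `transcript_status`, `protein_level_candidate`) and `summary` (per
#'   class: `total`, `n_no_probe`, `n_de_excluded`, `n_candidates`).
#' @export
candidate_accounting <- function(classes, statuses) {
  stopifnot(is.data.frame(classes),
            all(c("protein_id", "class") %in% names(classes)))
  if (nrow(classes) == 0L) {
    return(list(
      table = data.frame(protein_id = character(0), class = character(0),
                         transcript_status = character(0),
                         protein_level_candidate = logical(0),
                         stringsAsFactors = FALSE),
      summary = data.frame(class = character(0), total = integer(0),
                           n_no_probe = integer(0), n_de_excluded = integer(0),
                           n_candidates = integer(0), stringsAsFactors = FALSE)
    ))
  }
  miss <- setdiff(classes$protein_id, names(statuses))
  if (length(miss)) {
    stop("no transcript status for: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  st <- unname(statuses[classes$protein_id])
  tab <- data.frame(
    protein_id = classes$protein_id,
    class = classes$class,
    transcript_status = st,
    protein_level_candidate = st == "unchanged",
    stringsAsFactors = FALSE
  )
  summ <- do.call(rbind, lapply(split(tab, tab$class), function(d) {
    data.frame(class = d$class[1L],
               total = nrow(d),
               n_no_probe = sum(d$transcript_status == "no_probe"),
               n_de_excluded = sum(d$transcript_status %in% c("up", "down")),
               n_candidates = sum(d$protein_level_candidate),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}
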