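#' Merge replicate runs into a non-redundant proteome
#'
#' A protein is accepted as detected when its local FDR is strictly below
#' `fdr_threshold` (percent) in at least one contributing run; the merged
#' proteome is the union of accepted proteins. Reports without a
#' `local_fdr_pct` column are taken as pre-filtered.
#'
#' @param reports List of run report data frames (`protein_id`, `spectra`,
#'   `local_fdr_pct`), or a single report.
#' @param fdr_threshold Local FDR cutoff in percent; strict `<` (default 1).
#' @param label Label for the merged proteome.
#' @param id_level `"isoform"` keeps identifiers as given; `"gene"` strips
#'   AGI isoform suffixes before comparing (for reconciling datasets with
#'   different isoform conventions).
#' @return Object of class `proteome`: list with `label`, `members` (sorted
#'   unique ids) and `provenance` (per-run accepted id lists).
#' @export
merge_runs <- function(reports, fdr_threshold = 1, label = "merged",
                       id_level = c("isoform", "gene")) {
  id_level <- match.arg(id_level)
  if (is.data.frame(reports)) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  accepted <- lapply(reports, function(r) {
    ids <- if ("local_fdr_pct" %in% names(r)) {
      r$protein_id[r$local_fdr_pct < fdr_threshold]
    } else {
      r$protein_id
    }
    normalize_ids(ids, id_level)
  })
  names(accepted) <- vapply(seq_along(reports), function(i) {
    attr(reports[[i]], "run_id") %||% paste0("run", i)
  }, character(1))
  new_proteome(label, sort(unique(unlist(accepted, use.names = FALSE))),
               provenance = accepted)
}

#' Detection-multiplicity partition of a merged proteome
#'
#' Counts, for m = 1..n_runs, the proteins detected (local FDR below
#' threshold) in exactly m of the runs — the numbers a Venn diagram of
#' replicate MS runs displays — together with each count's percentage of
#' the merged total (one decimal, half-up).
#'
#' @inheritParams merge_runs
#' @return Data frame: `n_runs` (multiplicity), `count`, `fraction_pct`.
#'   Counts sum to the merged proteome size.
#' @export
overlap_partition <- function(reports, fdr_threshold = 1,
                              id_level = c("isoform", "gene")) {
  id_level <- match.arg(id_level)
  stopifnot(is.list(reports), length(reports) >= 2L)
  prot <- merge_runs(reports, fdr_threshold, id_level = id_level)
  mult <- table(factor(unlist(lapply(prot$provenance, unique),
                              use.names = FALSE),
                       levels = prot$members))
  counts <- tabulate(as.integer(mult), nbins = length(reports))
  data.frame(
    n_runs = seq_along(reports),
    count = counts,
    fraction_pct = round_half_up(100 * counts / length(prot$members), 1L)
  )
}

#' Pool the in-house wild-type proteome with previous wild-type lists
#'
#' Unions the study's own wild-type proteome with previously published
#' wild-type protein lists into a pooled reference, and reports the own
#' dataset's contribution fraction (|own| / |pooled|).
#'
#' @param own_wt A `proteome` (or character vector of ids).
#' @param previous_wt_lists List of character vectors of protein ids (may be
#'   empty).
#' @param id_level Identifier level for the comparison; see [merge_runs()].
#' @return `proteome` with extra fields `own_size`, `pooled_size` and
#'   `contribution_pct` (one decimal, half-up).
#' @export
pool_wildtype <- function(own_wt, previous_wt_lists = list(),
                          id_level = c("isoform", "gene")) {
  id_level <- match.arg(id_level)
  own <- normalize_ids(proteome_members(own_wt), id_level)
  prev <- lapply(previous_wt_lists, normalize_ids, id_level = id_level)
  pooled <- sort(unique(c(own, unlist(prev, use.names = FALSE))))
  if (length(pooled) == 0L) stop("pooled wild-type proteome is empty", call. = FALSE)
  out <- new_proteome("pooled_wt", pooled,
                      provenance = c(list(own = own), prev))
  out$own_size <- length(unique(own))
  out$pooled_size <- length(pooled)
  out$contribution_pct <- round_half_up(100 * out$own_size / out$pooled_size, 1L)
  out
}

#' Proteins detected only in the mutant
#'
#' Set difference mutant minus reference: the proteins that accumulated to
#' detectability in the mutant but were never seen in the (pooled)
#' wild-type reference — the primary candidate class of the screen.
#'
#' @param mutant,reference `proteome`s or character vectors of ids.
#' @return Sorted character vector of mutant-only protein ids.
#' @export
mutant_only <- function(mutant, reference) {
  sort(setdiff(proteome_members(mutant), proteome_members(reference)))
}

new_proteome <- function(label, members, provenance = list()) {
  structure(list(label = label, members = members, provenance = provenance),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s': %d non-redundant proteins from %d source(s)\n",
              x$label, length(x$members), length(x$provenance)))
  invisible(x)
}

proteome_members <- function(x) {
  if (inherits(x, "proteome")) x$members else as.character(x)
}

#' Strip AGI isoform suffixes
#'
#' Maps isoform-level TAIR identifiers (`AT1G01010.2`) to gene-level AGI
#' codes (`AT1G01010`). Identifiers without a `.n` suffix pass through.
#'
#' @param ids Character vector of identifiers.
#' @return Character vector of gene-level identifiers.
#' @export
strip_isoform <- function(ids) {
  sub("\\.\\d+$", "", ids)
}

normalize_ids <- function(ids, id_level = "isoform") {
  ids <- as.character(ids)
  if (identical(id_level, "gene")) strip_isoform(ids) else ids
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages here use the
#' conventional half-up rule (27.45 -> 27.5).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
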