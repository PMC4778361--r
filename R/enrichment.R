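#' Count occurrences of an oligomer in promoter sequences
#'
#' Forward-strand scan by default; overlapping occurrences count (ACACAC in
#' CACACACA occurs twice). The ambiguity code N never matches. With
#' `both_strands = TRUE` occurrences of the reverse complement are added
#' (a promoter "contains" the motif if either strand matches).
#'
#' @param promoters [Biostrings::DNAStringSet] or character vector of
#'   sequences over ACGTN.
#' @param oligomer Single motif string over ACGT (conventionally a 6-mer).
#' @param both_strands Also count the reverse complement (default `FALSE`).
#' @return Named integer vector: `occurrences` (total, overlapping) and
#'   `promoters_with` (promoters containing >= 1 occurrence).
#' @export
count_motif <- function(promoters, oligomer, both_strands = FALSE) {
  if (length(oligomer) != 1L || grepl("[^ACGT]", toupper(oligomer)) ||
      !nzchar(oligomer)) {
    stop("oligomer must be a single ACGT string", call. = FALSE)
  }
  oligomer <- toupper(oligomer)
  if (!methods::is(promoters, "DNAStringSet")) {
    promoters <- Biostrings::DNAStringSet(toupper(promoters))
  }
  hits <- Biostrings::vcountPattern(oligomer, promoters, fixed = TRUE)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(oligomer)))
    hits <- hits + Biostrings::vcountPattern(rc, promoters, fixed = TRUE)
  }
  c(occurrences = sum(hits), promoters_with = sum(hits > 0L))
}

#' Binomial probability for promoter-motif enrichment
#'
#' Given k of n query promoters containing a motif, and K of N background
#' promoters containing it, the background containment rate is p0 = K/N and
#' the reported statistic is the binomial point probability
#' P(X = k) = C(n,k) p0^k (1-p0)^(n-k), evaluated in log space for
#' stability. `tail = TRUE` gives the upper-tail probability P(X >= k)
#' instead (log-space sum of point terms). Occurrence counts do not enter
#' the statistic; only promoter-containing counts do.
#'
#' Degenerate background: with K = 0, zero successes are certain, so k = 0
#' returns 1 and k > 0 returns 0 with a warning.
#'
#' @param k Query promoters containing the motif (vectorised).
#' @param n Total query promoters.
#' @param K Background promoters containing the motif (vectorised).
#' @param N Total background promoters.
#' @param tail Return P(X >= k) instead of P(X = k) (default `FALSE`).
#' @return Numeric vector of probabilities.
#' @examples
#' binomial_motif_p(12, 42, 3253, 33602)  # 3.53e-04
#' @export
binomial_motif_p <- function(k, n, K, N, tail = FALSE) {
  stopifnot(n >= 1, N >= 1, all(k >= 0), all(k <= n), all(K >= 0), all(K <= N))
  m <- max(length(k), length(K))
  k <- rep_len(as.numeric(k), m)
  K <- rep_len(as.numeric(K), m)
  p0 <- K / N
  if (any(K == 0 & k > 0)) {
    warning("motif absent from background but present in query: probability 0",
            call. = FALSE)
  }
  point_log <- function(k, p0) {
    # guard the 0*log(0) cases explicitly
    lp <- lchoose(n, k)
    lp <- lp + ifelse(k == 0, 0, k * log(p0))
    lp + ifelse(k == n, 0, (n - k) * log1p(-p0))
  }
  if (!tail) {
    out <- numeric(m)
    for (i in seq_len(m)) {
      out[i] <- if (p0[i] == 0) as.numeric(k[i] == 0)
        else if (p0[i] == 1) as.numeric(k[i] == n)
        else exp(point_log(k[i], p0[i]))
    }
    return(out)
  }
  vapply(seq_len(m), function(i) {
    if (p0[i] == 0) return(as.numeric(k[i] == 0))
    if (p0[i] == 1) return(1)
    lps <- point_log(seq(k[i], n), p0[i])
    mx <- max(lps)
    exp(mx) * sum(exp(lps - mx))
  }, numeric(1))
}

#' Exhaustively score and rank all hexamers in query promoters
#'
#' Scores every 4^6 = 4096 hexamer by [binomial_motif_p()] on promoter-
#' containing counts in the query set against the background set, and
#' returns the `top` most enriched, sorted ascending by probability with
#' lexicographic tie-breaking. Occurrence totals are reported alongside
#' but do not enter the statistic. Windows containing N are ignored.
#'
#' @param query_promoters,background_promoters [Biostrings::DNAStringSet]s
#'   or character vectors (same nominal promoter length class).
#' @param top Number of motifs to return (default 5).
#' @param width Motif width (default 6).
#' @param both_strands Count both strands (default `FALSE`).
#' @param tail Use the upper-tail probability (default `FALSE`, point).
#' @return Data frame: `oligomer`, `query_occurrences`,
#'   `background_occurrences`, `query_promoters_with`, `n_query`,
#'   `background_promoters_with`, `n_background`, `p_value`.
#' @export
rank_motifs <- function(query_promoters, background_promoters, top = 5L,
                        width = 6L, both_strands = FALSE, tail = FALSE) {
  qy <- as_dna(query_promoters)
  bg <- as_dna(background_promoters)
  if (length(qy) == 0L) stop("empty query promoter set", call. = FALSE)
  if (length(bg) == 0L) stop("empty background promoter set", call. = FALSE)
  if (top <= 0L) {
    return(kmer_stats(character(0), qy, bg)[0, ])
  }
  qc <- kmer_counts(qy, width, both_strands)
  bc <- kmer_counts(bg, width, both_strands)
  p <- suppressWarnings(
    binomial_motif_p(qc$with, length(qy), bc$with, length(bg), tail = tail)
  )
  out <- data.frame(
    oligomer = qc$kmer,
    query_occurrences = qc$occ,
    background_occurrences = bc$occ,
    query_promoters_with = qc$with,
    n_query = length(qy),
    background_promoters_with = bc$with,
    n_background = length(bg),
    p_value = p,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$oligomer), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}

kmer_counts <- function(seqs, width, both_strands) {
  m <- Biostrings::oligonucleotideFrequency(seqs, width = width)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(colnames(m))))
    m <- m + m[, match(rc, colnames(m)), drop = FALSE]
  }
  list(kmer = colnames(m), occ = unname(colSums(m)),
       with = unname(colSums(m > 0L)))
}

kmer_stats <- function(kmer, qy, bg) {
  data.frame(oligomer = kmer, query_occurrences = integer(0),
             background_occurrences = integer(0),
             query_promoters_with = integer(0), n_query = integer(0),
             background_promoters_with = integer(0), n_background = integer(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(toupper(x))
}

#' GO-term overrepresentation by Fisher's exact test
#'
#' One-sided (enrichment) Fisher's exact test per GO term on the 2x2 table
#' (query-with-term, query-without, background-only-with-term,
#' background-only-without). Annotations are restricted to the background;
#' terms annotating no background gene are skipped with a warning. Raw
#' p-values, no multiple-testing correction.
#'
#' @param annotations Data frame with columns `gene_id`, `term_id` (one row
#'   per gene-term pair).
#' @param query_genes Character vector, must be a subset of
#'   `background_genes`.
#' @param background_genes Character vector defining the reference universe
#'   (e.g. all genes represented on the expression array).
#' @param alpha Significance level for the `enriched` flag (default 0.05).
#' @return Data frame: `term_id`, `query_hits`, `query_size`,
#'   `background_hits`, `background_size`, `p_value`, `enriched`; sorted
#'   ascending by p-value.
#' @export
fisher_go <- function(annotations, query_genes, background_genes,
                      alpha = 0.05) {
  stopifnot(is.data.frame(annotations),
            all(c("gene_id", "term_id") %in% names(annotations)))
  query_genes <- unique(as.character(query_genes))
  background_genes <- unique(as.character(background_genes))
  if (!all(query_genes %in% background_genes)) {
    stop("query genes must be a subset of the background", call. = FALSE)
  }
  ann <- unique(annotations[, c("gene_id", "term_id")])
  dropped <- !(ann$gene_id %in% background_genes)
  if (all(dropped) && nrow(ann) > 0L) {
    warning("no annotation maps to a background gene", call. = FALSE)
  }
  ann <- ann[!dropped, , drop = FALSE]
  n_q <- length(query_genes)
  n_b <- length(background_genes)
  terms <- split(ann$gene_id, ann$term_id)
  res <- lapply(names(terms), function(tm) {
    genes <- terms[[tm]]
    bh <- length(genes)
    qh <- sum(genes %in% query_genes)
    tab <- matrix(c(qh, n_q - qh, bh - qh, (n_b - n_q) - (bh - qh)), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term_id = tm, query_hits = qh, query_size = n_q,
               background_hits = bh, background_size = n_b,
               p_value = p, enriched = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), query_hits = integer(0),
                      query_size = integer(0), background_hits = integer(0),
                      background_size = integer(0), p_value = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
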