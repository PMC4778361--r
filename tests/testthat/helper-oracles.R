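# Independent brute-force oracles. These deliberately re-derive results by
# literal enumeration, not by calling the implementation under test.

# Tryptic digestion: walk the sequence position by position, cutting after
# K/R unless the next residue is P; then apply the length filter.
oracle_digest <- function(sequence, min_length = 6) {
  res <- strsplit(toupper(sequence), "")[[1]]
  peps <- character(0)
  cur <- character(0)
  for (i in seq_along(res)) {
    cur <- c(cur, res[i])
    is_cut <- res[i] %in% c("K", "R") &&
      (i == length(res) || res[i + 1] != "P") && i < length(res)
    if (is_cut) {
      peps <- c(peps, paste(cur, collapse = ""))
      cur <- character(0)
    }
  }
  if (length(cur)) peps <- c(peps, paste(cur, collapse = ""))
  peps[nchar(peps) >= min_length]
}

# Random protein sequence (standard 20 amino acids)
random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# Overlapping motif occurrences by position-by-position comparison
oracle_motif_count <- function(seq, motif) {
  seq <- toupper(seq); motif <- toupper(motif)
  w <- nchar(motif)
  n <- nchar(seq)
  if (n < w) return(0L)
  sum(vapply(seq_len(n - w + 1L),
             function(i) substr(seq, i, i + w - 1L) == motif, logical(1)))
}

# One-sided (enrichment) Fisher p by exhaustive hypergeometric enumeration:
# P(X >= q) where X ~ Hypergeom(total = N, white = m term genes, drawn = n)
oracle_fisher_greater <- function(q, n_query, m_term, n_total) {
  ks <- max(0, n_query + m_term - n_total):min(n_query, m_term)
  probs <- choose(m_term, ks) * choose(n_total - m_term, n_query - ks) /
    choose(n_total, n_query)
  sum(probs[ks >= q])
}

# Pooled-variance two-sample two-sided t-test from first principles
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# Minimal run report constructor
make_report <- function(ids, spectra = NULL, fdr = 0.5, run_id = "r1",
                        genotype = "wild_type", include = TRUE) {
  df <- data.frame(protein_id = ids,
                   spectra = if (is.null(spectra)) rep(1L, length(ids)) else spectra,
                   local_fdr_pct = rep_len(fdr, length(ids)),
                   stringsAsFactors = FALSE)
  attr(df, "run_id") <- run_id
  attr(df, "genotype") <- genotype
  attr(df, "include_in_quant") <- include
  df
}
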