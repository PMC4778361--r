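test_that("motif counting is overlapping, forward-strand, N-aware", {
  expect_equal(count_motif("CACGTGCACGTG", "CACGTG"),
               c(occurrences = 2L, promoters_with = 1L))
  expect_equal(count_motif("AAAAAA", "CACGTG"),
               c(occurrences = 0L, promoters_with = 0L))
  expect_equal(unname(count_motif("CACACACA", "ACACAC")[1]),
               oracle_motif_count("CACACACA", "ACACAC"))
  # N never matches
  expect_equal(count_motif("CANGTGCACGTG", "CACGTG"),
               c(occurrences = 1L, promoters_with = 1L))
  # both strands adds the reverse complement
  expect_equal(unname(count_motif("ACGTAA", "TTACGT", both_strands = TRUE)[1]), 1L)
  expect_error(count_motif("ACGT", "CACGUG"), "ACGT")
})

test_that("overlapping counts match the brute-force scanner on random sequences", {
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
      motif <- paste(sample(c("A", "C"), 6, replace = TRUE), collapse = "")
      expect_equal(unname(count_motif(s, motif)[1]),
                   oracle_motif_count(s, motif))
    }
  })
})

test_that("binomial point probabilities agree with dbinom and handle edges", {
  withr::with_seed(6, {
    for (i in 1:30) {
      n <- sample(1:100, 1); k <- sample(0:n, 1)
      N <- sample(100:50000, 1); K <- sample(0:N, 1)
      expect_equal(suppressWarnings(binomial_motif_p(k, n, K, N)),
                   dbinom(k, n, K / N), tolerance = 1e-10)
      expect_equal(binomial_motif_p(k, n, K, N, tail = TRUE),
                   pbinom(k - 1, n, K / N, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })
  # degenerate backgrounds
  expect_equal(binomial_motif_p(0, 10, 0, 100), 1)
  expect_warning(p0 <- binomial_motif_p(3, 10, 0, 100), "absent")
  expect_equal(p0, 0)
  expect_equal(binomial_motif_p(10, 10, 100, 100), 1)
})

test_that("point probabilities normalize over k and stay stable in log space", {
  for (n in c(10, 42, 74, 100)) {
    p <- binomial_motif_p(0:n, n, 3253, 33602)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # log-space route vs direct products, 10+ significant digits
  direct <- choose(74, 24) * (3253 / 33602)^24 * (1 - 3253 / 33602)^50
  expect_equal(binomial_motif_p(24, 74, 3253, 33602), direct,
               tolerance = 1e-10)
})

test_that("motif ranking finds a planted hexamer and is order-invariant", {
  cfg <- simulation_config(seed = 8, planted_motif_rate = 1,
                           n_query_promoters = 30,
                           n_background_promoters = 500)
  pr <- generate_promoters(cfg)
  rk <- rank_motifs(pr$query, pr$background, top = 5)
  expect_equal(rk$oligomer[1], "CACGTG")
  expect_equal(rk$query_promoters_with[1], 30L)

  perm <- withr::with_seed(1, sample(length(pr$query)))
  rk2 <- rank_motifs(pr$query[perm], pr$background, top = 5)
  expect_equal(rk2, rk)

  expect_equal(nrow(rank_motifs(pr$query, pr$background, top = 0)), 0L)
  expect_error(rank_motifs(Biostrings::DNAStringSet(), pr$background), "empty")
})

test_that("null query shows no systematic enrichment", {
  # query drawn from the background distribution: the smallest point
  # probability over 4096 motifs should not be extreme
  cfg <- simulation_config(seed = 12, planted_motif_rate = 0,
                           n_query_promoters = 42,
                           n_background_promoters = 1500)
  pr <- generate_promoters(cfg)
  rk <- rank_motifs(pr$query, pr$background, top = 4096)
  expect_gt(min(rk$p_value), 1e-8)
  # and the planted motif itself is nothing special
  expect_gt(rk$p_value[rk$oligomer == cfg$planted_motif], 1e-6)
})

test_that("Fisher GO test equals exhaustive hypergeometric enumeration", {
  ann <- data.frame(
    gene_id = c(sprintf("G%02d", 1:10), sprintf("G%02d", 1:25)),
    term_id = rep(c("GO:A", "GO:B"), c(10, 25)), stringsAsFactors = FALSE)
  bg <- sprintf("G%02d", 1:50)
  qy <- c("G01", "G02", "G03", "G30", "G31")
  res <- fisher_go(ann, qy, bg)
  a <- res[res$term_id == "GO:A", ]
  expect_equal(a$query_hits, 3L)
  expect_equal(a$p_value, oracle_fisher_greater(3, 5, 10, 50))
  b <- res[res$term_id == "GO:B", ]
  expect_equal(b$p_value, oracle_fisher_greater(b$query_hits, 5, 25, 50))
})

test_that("Fisher enrichment p equals enumeration on all small tables", {
  # exhaustive sweep over 2x2 tables with margins <= 10 through fisher_go
  # itself (the acceptance suite extends the margins to 30)
  for (N in c(6, 10)) {
    bg <- sprintf("G%02d", seq_len(N))
    for (n in 1:(N - 1)) {
      qy <- bg[seq_len(n)]
      for (m in 1:N) {
        for (q in max(0, n + m - N):min(n, m)) {
          term_genes <- c(qy[seq_len(q)],
                          setdiff(bg, qy)[seq_len(m - q)])
          ann <- data.frame(gene_id = term_genes, term_id = "T",
                            stringsAsFactors = FALSE)
          expect_equal(fisher_go(ann, qy, bg)$p_value,
                       oracle_fisher_greater(q, n, m, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("degenerate GO tables give p = 1", {
  ann <- data.frame(gene_id = sprintf("G%02d", 1:20),
                    term_id = "GO:ALL", stringsAsFactors = FALSE)
  bg <- sprintf("G%02d", 1:20)
  expect_equal(fisher_go(ann, c("G01", "G05"), bg)$p_value, 1)
  # query = background: every term has p = 1
  expect_true(all(fisher_go(ann, bg, bg)$p_value == 1))
  # annotation outside the background is skipped
  expect_error(fisher_go(ann, "X01", bg), "subset")
})
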