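make_matrix <- function(wt, mut, genes = NULL) {
  m <- cbind(wt, mut)
  rownames(m) <- genes %||% sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- c(paste0("wt_", seq_len(ncol(wt))),
                   paste0("mut_", seq_len(ncol(mut))))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a
grp <- function(n_wt, n_mut) c(rep("wild_type", n_wt), rep("mutant", n_mut))

test_that("identical groups are unchanged; a 2.2-fold gene is called up", {
  m <- make_matrix(matrix(1, 2, 4), matrix(1, 2, 3))
  de <- differential_expression(m, grp(4, 3))
  expect_equal(de$fold, c(1, 1))
  expect_equal(de$status, c("unchanged", "unchanged"))

  # the one mutant-higher protein excluded by its transcript: fold 2.2, p < 0.05
  withr::with_seed(42, {
    m2 <- make_matrix(matrix(1, 1, 4),
                      matrix(2.2 + rnorm(3, 0, 1e-3), 1, 3))
  })
  de2 <- differential_expression(m2, grp(4, 3))
  expect_equal(de2$fold, 2.2, tolerance = 1e-3)
  expect_lt(de2$p_value, 0.05)
  expect_equal(de2$status, "up")
})

test_that("t statistic and p match the closed-form pooled oracle and t.test", {
  wt <- c(1, 2, 3, 4); mut <- c(2, 4, 6)
  m <- make_matrix(matrix(wt, 1), matrix(mut, 1))
  de <- differential_expression(m, grp(4, 3))
  orc <- oracle_pooled_t(wt, mut)
  expect_equal(de$t_stat, orc$t)
  expect_equal(de$p_value, orc$p)
  ref <- t.test(mut, wt, var.equal = TRUE)
  expect_equal(de$p_value, ref$p.value)

  # Welch option against t.test
  dew <- differential_expression(m, grp(4, 3), var_equal = FALSE)
  refw <- t.test(mut, wt)
  expect_equal(dew$p_value, refw$p.value)
  expect_equal(dew$df, unname(refw$parameter))
})

test_that("status rules: joint criteria, inclusive boundaries, down calls", {
  # symmetric jitter keeps each group mean exact, so the folds land exactly
  # on the inclusive boundaries
  jit <- function(x, n) x + c(1e-5, -1e-5, rep(0, n - 2))
  m <- make_matrix(
    rbind(jit(1, 4), jit(1, 4), jit(1, 4), jit(1, 4)),
    rbind(jit(2, 3), jit(1.9, 3), jit(0.5, 3), jit(1, 3)))
  de <- differential_expression(m, grp(4, 3))
  expect_equal(de$status, c("up", "unchanged", "down", "unchanged"))
  expect_equal(de$fold, c(2, 1.9, 0.5, 1))

  # significance without a 2-fold change is not enough
  expect_lt(de$p_value[2], 0.05)
})

test_that("scaling the matrix leaves every status unchanged", {
  cfg <- simulation_config(seed = 3, n_genes = 300, planted_de_fraction = 0.1,
                           de_fold = 4)
  ex <- generate_expression(cfg)
  de1 <- differential_expression(ex$matrix, ex$groups)
  de2 <- differential_expression(ex$matrix * 37.5, ex$groups)
  expect_identical(de1$status, de2$status)
  expect_equal(de2$fold, de1$fold)
})

test_that("log2-scale input computes fold as back-transformed mean difference", {
  m <- make_matrix(matrix(3, 1, 4), matrix(4.2, 1, 3))  # log2 values
  de <- differential_expression(m, grp(4, 3), log2_input = TRUE)
  expect_equal(de$fold, 2^1.2)
})

test_that("zero wild-type mean flags the gene and excludes it from calls", {
  m <- make_matrix(matrix(0, 1, 4), matrix(c(1, 1.1, 0.9), 1, 3))
  expect_warning(de <- differential_expression(m, grp(4, 3)), "non-positive")
  expect_true(de$fold_undefined)
  expect_true(is.na(de$fold))
  expect_equal(de$status, "unchanged")
})

test_that("transcript status maps isoforms to gene-level DE calls", {
  de <- data.frame(gene_id = c("AT1G00010", "AT2G33380"),
                   status = c("unchanged", "up"), stringsAsFactors = FALSE)
  probes <- c("AT1G00010", "AT2G33380")
  st <- transcript_status(c("AT1G00010.1", "AT2G33380.1", "AT9G99999.1"),
                          de, probes)
  expect_identical(unname(st), c("unchanged", "up", "no_probe"))
})

test_that("candidate accounting reproduces the class arithmetic", {
  # mutant-only class: 236 proteins, 11 without probes, none DE -> 225
  ids_only <- sprintf("O%03d.1", 1:236)
  st_only <- setNames(rep("unchanged", 236), ids_only)
  st_only[1:11] <- "no_probe"
  # mutant-higher class: 322 proteins, 12 without probes, 1 up -> 309
  ids_high <- sprintf("H%03d.1", 1:322)
  st_high <- setNames(rep("unchanged", 322), ids_high)
  st_high[1:12] <- "no_probe"
  st_high[13] <- "up"
  acc <- candidate_accounting(
    data.frame(protein_id = c(ids_only, ids_high),
               class = rep(c("mutant_only", "mutant_higher"), c(236, 322))),
    c(st_only, st_high))
  s <- acc$summary
  expect_equal(s$n_candidates[s$class == "mutant_only"], 225L)
  expect_equal(s$n_candidates[s$class == "mutant_higher"], 309L)
  # per class: candidates + no-probe + DE-excluded = class size
  expect_equal(s$n_candidates + s$n_no_probe + s$n_de_excluded, s$total)

  # empty input gives an empty accounting
  empty <- candidate_accounting(
    data.frame(protein_id = character(0), class = character(0)),
    setNames(character(0), character(0)))
  expect_equal(nrow(empty$table), 0L)
  expect_equal(nrow(empty$summary), 0L)
})

test_that("type-I error is calibrated on a null simulation", {
  cfg <- simulation_config(seed = 17, n_genes = 2000, planted_de_fraction = 0,
                           no_probe_fraction = 0)
  ex <- generate_expression(cfg)
  de <- differential_expression(ex$matrix, ex$groups)
  frac <- mean(de$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(ex$matrix))
  expect_lt(abs(frac - 0.05), 1.96 * se + 1e-12)
})
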