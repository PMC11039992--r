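test_that("worked 2x2 example: folds and exact tail probabilities", {
  ev <- events_for_table(k = 5, n = 10, K = 10, N = 110)
  res <- enrichment_test(ev, "AA")
  expect_identical(unname(res$counts), c(5L, 10L, 10L, 110L))
  expect_equal(res$fold_vs_background, (5 / 10) / (5 / 100))  # = 10
  expect_equal(res$fold_vs_overall, (5 / 10) / (10 / 110))
  expect_equal(res$p_upper, oracle_hyper_upper(5, 10, 110, 10),
               tolerance = 1e-12)
  expect_equal(res$p_lower, oracle_hyper_lower(5, 10, 110, 10),
               tolerance = 1e-12)
})

test_that("null composition gives fold 1 and an upper tail >= 0.5", {
  ev <- events_for_table(k = 4, n = 20, K = 24, N = 120)
  res <- enrichment_test(ev, "AA")
  expect_equal(res$fold_vs_background, 1)
  expect_equal(res$fold_vs_overall, 1)
  expect_gte(res$p_upper, 0.5)
})

test_that("total depletion gives fold 0 and the lower tail P[X <= 0]", {
  ev <- events_for_table(k = 0, n = 10, K = 15, N = 100)
  res <- enrichment_test(ev, "AA")
  expect_equal(res$fold_vs_background, 0)
  expect_equal(res$p_lower, oracle_hyper_lower(0, 15, 100, 10),
               tolerance = 1e-12)
  expect_equal(res$p_upper, 1)
})

test_that("empty strata are rejected", {
  ev <- data.frame(event_type = "AA", class = "WITHIN_U12")
  expect_error(enrichment_test(ev, "AA"), "non-empty")
  expect_error(enrichment_test(data.frame(event_type = "AA"), "AA"),
               "class")
})

test_that("tail p-values match enumeration at larger N too", {
  for (case in list(c(12, 40, 60, 200), c(3, 25, 80, 500),
                    c(30, 50, 100, 400))) {
    ev <- events_for_table(case[1], case[2], case[3], case[4])
    res <- enrichment_test(ev, "AA")
    expect_equal(res$p_upper,
                 oracle_hyper_upper(case[1], case[3], case[4], case[2]),
                 tolerance = 1e-12)
    expect_equal(res$p_lower,
                 oracle_hyper_lower(case[1], case[3], case[4], case[2]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is available behind a flag", {
  cfg <- as_event_config(n_genes = 80, n_events = 1000,
                         aa_enrichment_fold = 3, seed = 4)
  gm <- simulate_gene_models(cfg)
  ev <- simulate_as_events(cfg, gm$u12_introns, gm$exons)
  cls <- classify_events(ev, gm$u12_introns, gm$exons)$events
  res <- enrichment_test(cls, "AA", bh_types = c("AA", "AD", "CE", "RI"))
  padj <- attr(res, "p_adjusted")
  expect_length(padj, 4)
  expect_true(all(padj >= 0 & padj <= 1))
})

make_ir <- function(ratios, depths, genes = NULL) {
  n <- length(ratios)
  data.frame(intron_id = sprintf("i%02d", seq_len(n)),
             gene_id = genes %||% sprintf("g%02d", seq_len(n)),
             ir_ratio = ratios, depth = depths, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical IR tables call nothing", {
  a <- make_ir(c(0.1, 0.5, 0.9), c(50, 50, 50))
  res <- differential_ir(a, a, min_delta = 0.1, min_depth = 10)
  expect_equal(res$n_gained, 0)
  expect_equal(res$n_lost, 0)
})

test_that("IR boundary: delta exactly at min_delta is not called", {
  a <- make_ir(c(0.2, 0.2), c(50, 50))
  b <- make_ir(c(0.3, 0.31), c(50, 50))
  res <- differential_ir(a, b, min_delta = 0.1, min_depth = 10)
  expect_identical(res$introns$call, c("none", "gained"))
})

test_that("the 20-intron fixture matches manual threshold application", {
  set.seed(33)
  genes <- rep(sprintf("g%02d", 1:10), each = 2)
  ra <- round(runif(20, 0, 0.8), 2)
  shift <- c(rep(0.25, 4), rep(-0.25, 4), rep(0.02, 12))
  depth_a <- c(rep(50, 18), 5, 50)
  depth_b <- c(5, rep(50, 19))
  rb <- pmin(pmax(ra + shift, 0), 1)
  a <- make_ir(ra, depth_a, genes)
  b <- make_ir(rb, depth_b, genes)
  res <- differential_ir(a, b, min_delta = 0.1, min_depth = 10)
  manual <- ifelse(depth_a >= 10 & depth_b >= 10 & (rb - ra) > 0.1, "gained",
            ifelse(depth_a >= 10 & depth_b >= 10 & (ra - rb) > 0.1, "lost",
                   "none"))
  expect_identical(res$introns$call, manual)
  # gene summary counts equal manual per-gene reduction
  per_gene <- tapply(seq_len(20), genes, function(i) {
    called <- i[manual[i] != "none"]
    if (length(called) == 0) "none"
    else manual[called[which.max(abs((rb - ra)[called]))]]
  })
  expect_equal(res$n_gained, sum(per_gene == "gained"))
  expect_equal(res$n_lost, sum(per_gene == "lost"))
})

test_that("key mismatches between IR tables are rejected", {
  a <- make_ir(c(0.1, 0.2), c(50, 50))
  b <- make_ir(c(0.1, 0.2, 0.3), c(50, 50, 50))
  expect_error(differential_ir(a, b), "identical intron sets")
  expect_error(differential_ir(a, a, min_delta = 0), "min_delta")
})
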