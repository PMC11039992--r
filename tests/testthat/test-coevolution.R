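test_that("membership tables binarize, reject duplicates, and round-trip", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("og_id\tsp1\tsp2\tsp3",
               "ogA\t0\t1\t3",
               "ogB\t1\t1\t1"), path)
  m <- build_profiles(path)
  expect_identical(as.integer(m["ogA", ]), c(0L, 1L, 1L))
  expect_identical(as.integer(m["ogB", ]), c(1L, 1L, 1L))
  expect_identical(colnames(m), c("sp1", "sp2", "sp3"))

  out <- tempfile(fileext = ".tsv")
  write_profiles(m, out)
  expect_identical(unclass(build_profiles(out)), unclass(m))

  writeLines(c("og_id\tsp1", "dup\t1", "dup\t0"), path)
  expect_error(build_profiles(path), "duplicate OG")
  writeLines("og_id\tsp1", path)
  expect_error(build_profiles(path), "empty")
})

test_that("cosine distance matches hand arithmetic and is symmetric", {
  expect_equal(cosine_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "all-zero")
  expect_error(cosine_distance(c(1, 0, 0), c(1, 0)), "equal length")
  set.seed(42)
  for (i in 1:25) {
    p <- rbinom(8, 1, 0.5); q <- rbinom(8, 1, 0.5)
    if (sum(p) == 0 || sum(q) == 0) next
    d <- cosine_distance(p, q)
    expect_equal(d, cosine_distance(q, p))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, oracle_cosine(p, q))
  }
})

test_that("ranking puts duplicates first, breaks ties lexicographically, and flags unrankable rows", {
  m <- pa_from_rows(rbind(q = c(1, 1, 0, 1),
                       dup = c(1, 1, 0, 1),
                       tieB = c(1, 0, 0, 0),
                       tieA = c(0, 1, 0, 0),
                       zero = c(0, 0, 0, 0)))
  r <- rank_coevolution("q", m)
  expect_identical(r$entries$og_id[1], "dup")
  expect_equal(r$entries$distance[1], 0)
  # tieA and tieB sit at the same distance; lexicographic order decides
  d <- r$entries$distance
  expect_equal(d[2], d[3])
  expect_identical(r$entries$og_id[2:3], c("tieA", "tieB"))
  expect_identical(r$unrankable, "zero")
  expect_error(rank_coevolution("nope", m), "not in matrix")
  expect_error(rank_coevolution("zero", m), "all-zero")
})

test_that("ranking equals the brute-force oracle and ignores row order", {
  set.seed(7)
  for (i in 1:20) {
    n_og <- sample(3:8, 1); n_sp <- sample(2:6, 1)
    m <- matrix(rbinom(n_og * n_sp, 1, 0.5), n_og,
                dimnames = list(sprintf("og%02d", seq_len(n_og)),
                                sprintf("sp%02d", seq_len(n_sp))))
    m[1, ] <- pmax(m[1, ], rbinom(n_sp, 1, 0.6))
    if (sum(m[1, ]) == 0) m[1, 1] <- 1
    pm <- pa_matrix(m)
    r <- rank_coevolution("og01", pm)
    o <- oracle_ranking("og01", m)
    expect_identical(r$entries$og_id, o$og_id)
    expect_equal(r$entries$distance, o$distance, tolerance = 1e-12)
    expect_identical(r$unrankable, o$unrankable)
    # row permutation leaves the ranking unchanged
    perm <- sample(nrow(m))
    r2 <- rank_coevolution("og01", pa_matrix(m[perm, , drop = FALSE]))
    expect_identical(r2$entries, r$entries)
  }
})

test_that("recovery report: ranks, top-k and AUC against the pair-counting oracle", {
  m <- pa_from_rows(rbind(q = c(1, 1, 1, 0),
                       a = c(1, 1, 1, 0),
                       b = c(1, 1, 0, 0),
                       c = c(1, 0, 0, 0),
                       d = c(0, 0, 1, 1),
                       e = c(0, 1, 0, 1)))
  r <- rank_coevolution("q", m)
  rec <- evaluate_recovery(r, c("a", "b"), k = 2)
  expect_identical(unname(rec$ranks[c("a", "b")]), c(1L, 2L))
  expect_equal(rec$top_k_hits, 2)
  expect_equal(rec$auc, 1)

  d <- setNames(r$entries$distance, r$entries$og_id)
  rec2 <- evaluate_recovery(r, c("a", "d"), k = 1)
  expect_equal(rec2$auc, oracle_auc(d[c("a", "d")], d[c("b", "c", "e")]))
  expect_error(evaluate_recovery(r, character(), 3), "non-empty")
  expect_error(evaluate_recovery(r, "unknown", 3), "absent")
})

test_that("interleaved reference ranks give the closed-form AUC", {
  # synthetic ranking with distinct distances at ranks 1..6; reference at
  # the odd ranks -> AUC from explicit pair counting
  entries <- data.frame(og_id = sprintf("og%d", 1:6),
                        distance = seq(0.1, 0.6, by = 0.1),
                        rank = 1:6, stringsAsFactors = FALSE)
  rk <- structure(list(query_og = "q", entries = entries,
                       unrankable = character()),
                  class = "coevolution_ranking")
  rec <- evaluate_recovery(rk, c("og1", "og3", "og5"), k = 3)
  # pairs won by refs: og1 beats 3, og3 beats 2, og5 beats 1 of 9 pairs
  expect_equal(rec$auc, 6 / 9)
  expect_equal(rec$top_k_hits, 2)
})

test_that("unrankable reference members take the worst ranks", {
  m <- pa_from_rows(rbind(q = c(1, 1, 0), a = c(1, 1, 0),
                          b = c(0, 1, 0), z = c(0, 0, 0)))
  r <- rank_coevolution("q", m)
  rec <- evaluate_recovery(r, c("a", "z"), k = 1)
  expect_identical(unname(rec$ranks[c("a", "z")]), c(1L, 3L))
  expect_equal(rec$top_k_hits, 1)
  # z ties with nothing better than rank 3; AUC = mean of win fractions
  d_b <- r$entries$distance[r$entries$og_id == "b"]
  expect_equal(rec$auc, oracle_auc(c(0, Inf), d_b))
})

test_that("planted modules are tighter than background on average", {
  intra <- c(); inter <- c()
  mod <- sprintf("m%d", 1:5)
  for (s in 1:50) {
    tr <- simulate_tree(40, s)
    m <- simulate_gene_loss(tr, 30, loss_model(1, mod, 0.8), s + 500)
    ok <- rowSums(m) > 0
    mm <- mod[ok[mod]]
    bg <- intersect(sprintf("OG%05d", 1:30), rownames(m)[ok])
    if (length(mm) < 2 || length(bg) == 0) next
    q <- as.numeric(m[mm[1], ])
    intra <- c(intra, vapply(mm[-1], function(o) {
      cosine_distance(q, as.numeric(m[o, ]))
    }, numeric(1)))
    inter <- c(inter, vapply(bg, function(o) {
      cosine_distance(q, as.numeric(m[o, ]))
    }, numeric(1)))
  }
  expect_lt(mean(intra), mean(inter))
})
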