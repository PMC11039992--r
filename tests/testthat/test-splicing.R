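test_that("annotation merging collapses exact duplicates and unions sources", {
  a <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600),
                  strand = "+", subtype = "GT-AG")
  b <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 601),
                  strand = "+", subtype = "GT-AG")
  merged <- merge_u12_annotations(dbA = a, dbB = b)
  expect_equal(nrow(merged), 3)
  shared <- merged[merged$start == 100, ]
  expect_identical(shared$sources, "dbA,dbB")
  # one-bp 3' difference stays two records: exact-match policy
  expect_equal(sum(merged$start == 500), 2)
})

test_that("merging matches a hand-computed set union and is idempotent", {
  l1 <- data.frame(chrom = "chr1", start = c(10, 30, 50, 70),
                   end = c(20, 40, 60, 80), strand = "+")
  l2 <- data.frame(chrom = "chr1", start = c(10, 30, 50, 90, 110),
                   end = c(20, 40, 60, 100, 120), strand = "+")
  l3 <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr1"),
                   start = c(10, 30, 50, 10, 30, 130),
                   end = c(20, 40, 60, 20, 40, 140), strand = "+")
  merged <- merge_u12_annotations(a = l1, b = l2, c = l3)
  # union by hand: {10,30,50,70} + {90,110} + {chr2:10, chr2:30, 130} = 9
  expect_equal(nrow(merged), 9)
  expect_false(is.unsorted(order(merged$chrom, merged$start)))
  again <- merge_u12_annotations(m = merged, m2 = merged)
  expect_identical(again[c("chrom", "start", "end", "strand", "subtype",
                           "sources")],
                   merged[c("chrom", "start", "end", "strand", "subtype",
                            "sources")])
  bad <- data.frame(chrom = "chr1", start = 10, end = 10, strand = "+")
  expect_error(merge_u12_annotations(x = bad), "start >= end")
})

test_that("BED reading is strict about coordinates, strand, and line numbers", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tGT-AG\t0\t+",
               "chr1\t300\t300\tGT-AG\t0\t+"), path)
  expect_error(read_bed(path), "line 2.*start >= end")
  writeLines(c("chr1\t100\t200\tx\t0\tz"), path)
  expect_error(read_bed(path), "strand")
  writeLines(c("# comment", "chr1\t100\t200\tAT-AC\t0\t-"), path)
  bed <- read_bed(path)
  expect_identical(bed$strand, "-")
  expect_identical(bed$name, "AT-AC")
})

test_that("significance filtering uses strict thresholds and keeps order", {
  ev <- rbind(toy_event("A", 1, 2, pr = 0.95, dpsi = -0.10),
              toy_event("A", 3, 4, pr = 0.90, dpsi = 0.50),
              toy_event("A", 5, 6, pr = 0.95, dpsi = 0.05),
              toy_event("A", 7, 8, pr = 0.91, dpsi = 0.051),
              toy_event("A", 9, 10, pr = 0.89, dpsi = 0.9),
              toy_event("A", 11, 12, pr = 1.00, dpsi = 0.04))
  kept <- filter_significant_events(ev)
  expect_equal(kept$start, c(1, 7))
  # exact-threshold events are excluded (strict inequality on both rules)
  expect_false(3 %in% kept$start)
  expect_false(5 %in% kept$start)
})

test_that("filtering is monotone in both thresholds", {
  cfg <- as_event_config(n_genes = 30, n_events = 400, seed = 9)
  gm <- simulate_gene_models(cfg)
  ev <- simulate_as_events(cfg, gm$u12_introns, gm$exons)
  for (pr in c(0, 0.5, 0.9, 0.99)) {
    counts <- vapply(c(0, 0.05, 0.2, 0.5),
                     function(dp) nrow(filter_significant_events(ev, pr, dp)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  for (dp in c(0, 0.05, 0.3)) {
    counts <- vapply(c(0, 0.5, 0.9, 0.99),
                     function(pr) nrow(filter_significant_events(ev, pr, dp)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("classification matches exhaustive manual evaluation on the toy gene set", {
  gm <- toy_gene_models()
  u12 <- toy_u12_introns()
  cases <- list(
    list(ev = toy_event("A", 320, 340), want = "WITHIN_U12"),
    list(ev = toy_event("A", 290, 310), want = "WITHIN_U12"),
    list(ev = toy_event("A", 380, 420), want = "WITHIN_U12"),
    list(ev = toy_event("A", 210, 230), want = "PROXIMAL_U12"),
    list(ev = toy_event("A", 110, 130), want = "PROXIMAL_U12"),
    list(ev = toy_event("A", 510, 530), want = "PROXIMAL_U12"),
    list(ev = toy_event("A", 410, 430), want = "PROXIMAL_U12"),
    list(ev = toy_event("A", 610, 630), want = "U12_GENE_DISTAL"),
    list(ev = toy_event("A", 0, 50), want = "U12_GENE_DISTAL"),
    list(ev = toy_event("A", 320, 340, strand = "-"),
         want = "U12_GENE_DISTAL"),  # wrong strand: no U12 overlap counts
    list(ev = toy_event("B", 2210, 2230, strand = "-"),
         want = "U2_ONLY_BACKGROUND"),
    list(ev = toy_event("B", 2050, 2450, strand = "-"),
         want = "U2_ONLY_BACKGROUND"))
  for (cs in cases) {
    expect_identical(classify_event(cs$ev, u12, gm), cs$want)
  }
  # the whole table at once partitions into exactly one class per event
  ev <- do.call(rbind, lapply(cases, `[[`, "ev"))
  res <- classify_events(ev, u12, gm)
  expect_equal(nrow(res$events), nrow(ev))
  expect_identical(res$events$class, vapply(cases, `[[`, "", "want"))
  expect_equal(sum(table(res$events$class)), nrow(ev))
})

test_that("events in unknown genes go to the skip list", {
  gm <- toy_gene_models()
  res <- classify_events(toy_event("nope", 1, 10), toy_u12_introns(), gm)
  expect_equal(nrow(res$events), 0)
  expect_equal(nrow(res$skipped), 1)
  expect_match(res$skipped$reason, "not in gene models")
  expect_error(classify_event(toy_event("nope", 1, 10),
                              toy_u12_introns(), gm), "absent")
})
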