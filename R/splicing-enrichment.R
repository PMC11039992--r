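#' Hypergeometric enrichment of an event type at U12-type introns
#'
#' Tests whether events of one type (e.g. alternative acceptors, AA) are
#' over-represented among events at or immediately flanking U12-type
#' introns, relative to events in genes containing only major-type
#' introns. The universe is the union of the U12 stratum
#' (WITHIN_U12 + PROXIMAL_U12) and the background stratum
#' (U2_ONLY_BACKGROUND); U12_GENE_DISTAL events belong to neither
#' comparison group and are excluded from both.
#'
#' With `k` type-matching events among the `n` U12-stratum events, and `K`
#' type-matching among all `N` universe events, the report carries two fold
#' definitions (the headline "x-fold" construction is ambiguous between
#' them): `fold_vs_background = (k/n) / ((K-k)/(N-n))` — U12-stratum rate
#' over background rate — and `fold_vs_overall = (k/n) / (K/N)`.
#' P-values are exact hypergeometric tails: upper `P[X >= k]` for
#' enrichment, lower `P[X <= k]` for depletion, two-sided as
#' `min(1, 2 * min(tails))`.
#'
#' @param classified_events event data.frame with a `class` column
#'   ([classify_events()]`$events`); typically significance-filtered
#'   first.
#' @param event_type type code to test (e.g. `"AA"`).
#' @param bh_types optional character vector: when given, p-values for all
#'   these types are computed and Benjamini-Hochberg-adjusted upper-tail
#'   p-values attached as attribute `p_adjusted` (off by default; raw
#'   values are the primary report).
#' @return an `enrichment_result`: list with `event_type`, `counts`
#'   (k, n, K, N), `fold_vs_background`, `fold_vs_overall`, `p_upper`,
#'   `p_lower`, `p_two_sided`.
#' @export
enrichment_test <- function(classified_events, event_type,
                            bh_types = NULL) {
  if (!"class" %in% names(classified_events)) {
    stop("events must carry a `class` column from classify_events()",
         call. = FALSE)
  }
  in_u12 <- classified_events$class %in% c("WITHIN_U12", "PROXIMAL_U12")
  in_bg <- classified_events$class == "U2_ONLY_BACKGROUND"
  n <- sum(in_u12)
  n_bg <- sum(in_bg)
  if (n == 0L || n_bg == 0L) {
    stop("both the U12 stratum and the background stratum must be non-empty",
         call. = FALSE)
  }
  one_type <- function(type) {
    is_type <- classified_events$event_type == type
    k <- sum(is_type & in_u12)
    K <- k + sum(is_type & in_bg)
    N <- n + n_bg
    fold_bg <- if (K - k > 0) (k / n) / ((K - k) / (N - n))
               else if (k > 0) Inf else NaN
    fold_all <- if (K > 0) (k / n) / (K / N) else NaN
    p_up <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_lo <- stats::phyper(k, K, N - K, n)
    structure(list(event_type = type,
                   counts = c(k = k, n = n, K = K, N = N),
                   fold_vs_background = fold_bg,
                   fold_vs_overall = fold_all,
                   p_upper = p_up, p_lower = p_lo,
                   p_two_sided = min(1, 2 * min(p_up, p_lo))),
              class = "enrichment_result")
  }
  res <- one_type(event_type)
  if (!is.null(bh_types)) {
    raw <- vapply(bh_types, function(t) one_type(t)$p_upper, numeric(1))
    attr(res, "p_adjusted") <- stats::p.adjust(raw, method = "BH")
  }
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("%s enrichment at U12-type introns: %d/%d vs %d/%d background\n",
              x$event_type, ct[["k"]], ct[["n"]], ct[["K"]] - ct[["k"]],
              ct[["N"]] - ct[["n"]]))
  cat(sprintf("  fold vs background = %.3g, fold vs overall = %.3g\n",
              x$fold_vs_background, x$fold_vs_overall))
  cat(sprintf("  hypergeometric p: upper = %.3g, lower = %.3g, two-sided = %.3g\n",
              x$p_upper, x$p_lower, x$p_two_sided))
  invisible(x)
}

#' Differential intron retention summary
#'
#' Downstream counting step over per-intron IR ratios produced by external
#' tooling: an intron is called `gained` when `ir_b - ir_a > min_delta`
#' (strict) with supporting depth >= `min_depth` in both conditions, and
#' `lost` when `ir_a - ir_b > min_delta` under the same depth rule. Each
#' gene is summarized by its most extreme intron (largest |delta| among
#' depth-passing introns).
#'
#' @param ir_a,ir_b data.frames with columns `intron_id`, `gene_id`,
#'   `ir_ratio`, `depth`, keyed by identical intron sets.
#' @param min_delta IR-ratio change threshold, in (0, 1].
#' @param min_depth minimum supporting-read depth in both conditions.
#' @return list with `introns` (intron_id, gene_id, delta, call),
#'   `genes` (gene_id, delta, call), `n_gained`, `n_lost` (gene counts).
#' @export
differential_ir <- function(ir_a, ir_b, min_delta = 0.1, min_depth = 10) {
  if (min_delta <= 0 || min_delta > 1) {
    stop("`min_delta` must lie in (0, 1]", call. = FALSE)
  }
  for (tab in list(ir_a, ir_b)) {
    if (!all(c("intron_id", "gene_id", "ir_ratio", "depth") %in% names(tab))) {
      stop("IR tables need intron_id, gene_id, ir_ratio, depth",
           call. = FALSE)
    }
  }
  if (!setequal(ir_a$intron_id, ir_b$intron_id) ||
      anyDuplicated(ir_a$intron_id) || anyDuplicated(ir_b$intron_id)) {
    stop("IR tables must be keyed by identical intron sets", call. = FALSE)
  }
  b <- ir_b[match(ir_a$intron_id, ir_b$intron_id), , drop = FALSE]
  delta <- b$ir_ratio - ir_a$ir_ratio
  deep <- ir_a$depth >= min_depth & b$depth >= min_depth
  call <- rep("none", nrow(ir_a))
  call[deep & delta > min_delta] <- "gained"
  call[deep & -delta > min_delta] <- "lost"
  introns <- data.frame(intron_id = ir_a$intron_id, gene_id = ir_a$gene_id,
                        delta = delta, call = call,
                        stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(split(introns, introns$gene_id), function(g) {
    called <- g[g$call != "none", , drop = FALSE]
    top <- if (nrow(called) > 0L) called[which.max(abs(called$delta)), ]
           else g[which.max(abs(g$delta)), ]
    data.frame(gene_id = top$gene_id, delta = top$delta, call = top$call,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(introns = introns, genes = genes,
       n_gained = sum(genes$call == "gained"),
       n_lost = sum(genes$call == "lost"))
}
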