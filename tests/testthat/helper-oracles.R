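# Independent oracles and small fixtures shared across test files.
# Everything here is deliberately naive (loops, enumeration) so it cannot
# share a code path with the implementation it checks.

# cosine distance by explicit summation
oracle_cosine <- function(p, q) {
  dot <- 0; np <- 0; nq <- 0
  for (i in seq_along(p)) {
    dot <- dot + p[i] * q[i]
    np <- np + p[i]^2
    nq <- nq + q[i]^2
  }
  1 - dot / (sqrt(np) * sqrt(nq))
}

# brute-force ranking: all pairwise distances, sort by (distance, id)
oracle_ranking <- function(query, mat) {
  others <- setdiff(rownames(mat), query)
  q <- as.numeric(mat[query, ])
  ranked <- others[rowSums(mat[others, , drop = FALSE]) > 0]
  unrankable <- sort(setdiff(others, ranked))
  d <- vapply(ranked, function(og) {
    oracle_cosine(as.numeric(mat[og, ]), q)
  }, numeric(1))
  ord <- order(d, ranked)
  list(og_id = ranked[ord], distance = unname(d[ord]),
       unrankable = unrankable)
}

# upper/lower hypergeometric tails by explicit enumeration over all draws
oracle_hyper_upper <- function(k, K, N, n) {
  js <- max(0, k):min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}
oracle_hyper_lower <- function(k, K, N, n) {
  js <- max(0, n - (N - K)):min(k, K, n)
  if (k < max(0, n - (N - K))) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# AUC by explicit pair counting over assigned distances
oracle_auc <- function(d_ref, d_non) {
  tot <- 0
  for (a in d_ref) for (b in d_non) {
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(d_ref) * length(d_non))
}

# classified-event frame realizing a 2x2 table (k of n U12-stratum events
# are AA; K-k of N-n background events are AA)
events_for_table <- function(k, n, K, N) {
  data.frame(
    event_type = c(rep("AA", k), rep("CE", n - k),
                   rep("AA", K - k), rep("CE", (N - n) - (K - k))),
    class = c(rep("WITHIN_U12", n), rep("U2_ONLY_BACKGROUND", N - n)),
    stringsAsFactors = FALSE)
}

# one hand-built gene panel used by the classification tests:
# gene A (+, hosts a U12 intron), gene B (-, major introns only)
toy_gene_models <- function() {
  rbind(
    data.frame(gene_id = "A", chrom = "chr1",
               start = c(0, 200, 400, 600, 800),
               end = c(100, 300, 500, 700, 900),
               strand = "+", exon_rank = 1:5),
    data.frame(gene_id = "B", chrom = "chr1",
               start = c(2000, 2200, 2400),
               end = c(2100, 2300, 2500),
               strand = "-", exon_rank = 1:3))
}

toy_u12_introns <- function() {
  data.frame(chrom = "chr1", start = 300L, end = 400L, strand = "+",
             subtype = "AT-AC", sources = "toy", stringsAsFactors = FALSE)
}

toy_event <- function(gene_id, start, end, strand = "+",
                      event_type = "AA", dpsi = 0.2, pr = 0.99) {
  data.frame(gene_id = gene_id, event_type = event_type, chrom = "chr1",
             start = start, end = end, strand = strand,
             psi_a = 0.5, psi_b = 0.5 + dpsi, delta_psi = dpsi,
             probability = pr, stringsAsFactors = FALSE)
}

# presence/absence matrix from named rows, default species names
pa_from_rows <- function(m) {
  colnames(m) <- sprintf("sp%d", seq_len(ncol(m)))
  pa_matrix(m)
}

# all binary matrices with r rows x c cols, as a list (only for small r*c)
all_binary_matrices <- function(r, c) {
  n <- r * c
  lapply(0:(2^n - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    matrix(bits, nrow = r,
           dimnames = list(sprintf("og%02d", seq_len(r)),
                           sprintf("sp%02d", seq_len(c))))
  })
}
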