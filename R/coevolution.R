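#' Cosine distance between two phylogenetic profiles
#'
#' `1 - (p . q) / (||p|| ||q||)`. For binary presence/absence profiles the
#' value lies in `[0, 1]`: 0 for identical profiles, 1 for profiles with no
#' species in common. An all-zero profile has no direction, so its distance
#' is undefined and raises an error rather than silently returning 0 or 1.
#'
#' @param p,q numeric vectors of equal length (0/1 presence profiles).
#' @return cosine distance in `[0, 1]`.
#' @export
cosine_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  np <- sqrt(sum(p^2))
  nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) {
    stop("cosine distance undefined for an all-zero profile", call. = FALSE)
  }
  d <- 1 - sum(p * q) / (np * nq)
  min(max(d, 0), 1)
}

#' Rank orthologous groups by cosine distance to a query profile
#'
#' The co-evolution screen: every non-query OG with a non-zero profile is
#' scored by cosine distance to the query's profile and sorted ascending
#' (closest first). Ties are broken lexicographically by OG id, so the
#' ranking is deterministic across platforms. OGs with all-zero profiles
#' cannot be placed on the distance scale; they are reported separately as
#' `unrankable`, never interleaved.
#'
#' @param query_og OG id of the query (e.g. the gene whose co-evolving
#'   partners are sought); must be a row of `matrix` with a non-zero
#'   profile.
#' @param matrix a [pa_matrix].
#' @return a `coevolution_ranking`: list with `query_og`, `entries` (a
#'   data.frame `og_id`, `distance`, `rank`) and `unrankable` (character).
#' @export
rank_coevolution <- function(query_og, matrix) {
  stopifnot(inherits(matrix, "pa_matrix"))
  if (!query_og %in% rownames(matrix)) {
    stop("query OG not in matrix: ", query_og, call. = FALSE)
  }
  q <- as.numeric(matrix[query_og, ])
  if (sum(q) == 0) {
    stop("query profile is all-zero; distance undefined", call. = FALSE)
  }
  others <- rownames(matrix)[rownames(matrix) != query_og]
  m <- matrix[others, , drop = FALSE]
  rs <- rowSums(m)
  unrankable <- sort(others[rs == 0])
  ranked <- others[rs > 0]
  m <- m[ranked, , drop = FALSE]
  # vectorized cosine against the single query profile
  d <- 1 - as.numeric(m %*% q) / (sqrt(rowSums(m^2)) * sqrt(sum(q^2)))
  d <- pmin(pmax(d, 0), 1)
  ord <- order(d, ranked, method = "radix")
  entries <- data.frame(og_id = ranked[ord], distance = d[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(query_og = query_og, entries = entries,
                 unrankable = unrankable),
            class = "coevolution_ranking")
}

#' @export
print.coevolution_ranking <- function(x, n = 10, ...) {
  cat(sprintf("Co-evolution ranking for query '%s' (%d ranked, %d unrankable)\n",
              x$query_og, nrow(x$entries), length(x$unrankable)))
  print(utils::head(x$entries, n))
  invisible(x)
}

#' Score recovery of a reference gene set in a co-evolution ranking
#'
#' Quantifies how well known partners of the query (the reference set)
#' concentrate at the top of the ranking: their 1-based ranks, the number
#' inside the top `k`, and an AUC equal to the probability that a uniformly
#' random reference member outranks (has smaller cosine distance than) a
#' uniformly random non-reference member, ties counting 1/2. Unrankable
#' reference members are assigned rank worse than every ranked OG and
#' infinite distance.
#'
#' @param ranking a `coevolution_ranking` from [rank_coevolution()].
#' @param reference_set character vector of OG ids (subset of the ranking's
#'   universe), non-empty.
#' @param k top-`k` cutoff for the hit count.
#' @return a `recovery_report`: list with `reference_set`, `ranks` (named),
#'   `top_k_hits`, `k`, `auc`.
#' @export
evaluate_recovery <- function(ranking, reference_set, k) {
  stopifnot(inherits(ranking, "coevolution_ranking"))
  reference_set <- unique(as.character(reference_set))
  if (length(reference_set) == 0L) {
    stop("reference set must be non-empty", call. = FALSE)
  }
  universe <- c(ranking$entries$og_id, ranking$unrankable)
  missing <- setdiff(reference_set, universe)
  if (length(missing) > 0L) {
    stop("reference OGs absent from ranking: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_ranked <- nrow(ranking$entries)
  ranks <- c(stats::setNames(ranking$entries$rank, ranking$entries$og_id),
             stats::setNames(n_ranked + seq_along(ranking$unrankable),
                             ranking$unrankable))
  dist <- c(stats::setNames(ranking$entries$distance,
                            ranking$entries$og_id),
            stats::setNames(rep(Inf, length(ranking$unrankable)),
                            ranking$unrankable))
  is_ref <- names(dist) %in% reference_set
  dr <- dist[is_ref]
  dn <- dist[!is_ref]
  if (length(dn) == 0L) {
    stop("reference set covers the whole ranking; AUC undefined",
         call. = FALSE)
  }
  # P(ref outranks non-ref), ties at equal distance count 1/2 (Inf-Inf
  # pairs among unrankables are ties too)
  wins <- vapply(dr, function(d) {
    sum(d < dn) + 0.5 * sum(d == dn)
  }, numeric(1))
  auc <- sum(wins) / (length(dr) * length(dn))
  ref_ranks <- ranks[reference_set]
  structure(list(reference_set = reference_set, ranks = ref_ranks,
                 top_k_hits = sum(ref_ranks <= k), k = as.integer(k),
                 auc = auc),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery of %d reference OGs: %d in top %d, AUC = %.3f\n",
              length(x$reference_set), x$top_k_hits, x$k, x$auc))
  print(sort(x$ranks))
  invisible(x)
}

#' Write a co-evolution ranking as TSV
#'
#' Columns `og_id`, `distance`, `rank`; unrankable OGs follow with empty
#' distance and rank beyond the ranked block.
#'
#' @param ranking a `coevolution_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "coevolution_ranking"))
  df <- ranking$entries
  if (length(ranking$unrankable) > 0L) {
    df <- rbind(df, data.frame(og_id = ranking$unrankable,
                               distance = NA_real_,
                               rank = nrow(df) + seq_along(ranking$unrankable)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
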