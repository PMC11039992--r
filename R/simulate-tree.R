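#' Evaluate an expression under a fixed RNG seed
#'
#' All stochastic generators in the package funnel their randomness through
#' this helper: the global RNG state is saved, the seed applied, and the
#' previous state restored on exit, so a generator call is bit-reproducible
#' and leaves no footprint on the caller's RNG stream.
#'
#' @param seed a single finite integer-valued number.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a species tree under a Yule pure-birth process
#'
#' Stand-in for a curated eukaryote-wide species panel: a pure-birth
#' (Yule) tree with `n_species` extant leaves, rescaled so that the root
#' height is exactly 1 (the tree is ultrametric, so every root-to-tip path
#' has depth 1). Branch lengths are therefore in units of total tree
#' height, which makes loss rates directly interpretable as expected loss
#' events from root to tip.
#'
#' @param n_species number of extant species (leaves), at least 2.
#' @param seed RNG seed; a fixed seed yields a byte-identical tree.
#' @return an [ape::phylo] object with unique tip labels `s001`, `s002`, ...
#' @export
simulate_tree <- function(n_species, seed) {
  if (length(n_species) != 1L || !is.finite(n_species) || n_species < 2) {
    stop("`n_species` must be a single integer >= 2", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n_species)])
  tree$edge.length <- tree$edge.length / height
  tree$tip.label <- sprintf("s%03d", seq_len(n_species))
  tree
}
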