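#' Loss model for Dollo gene-loss simulation
#'
#' Parameters of the lineage-specific gene-loss process used by
#' [simulate_gene_loss()]. `lambda` is the per-OG loss rate in events per
#' unit branch length; `module_members` names a set of co-functioning OGs
#' whose losses are correlated; `rho` is the per-branch probability that
#' the whole module shares a single loss indicator on that branch (at
#' `rho = 1` module profiles are identical, at `rho = 0` module members are
#' independent).
#'
#' @param lambda loss rate, >= 0.
#' @param module_members character vector of module OG ids (may be empty
#'   when `rho = 0`).
#' @param rho module loss-correlation in `[0, 1]`.
#' @return a `loss_model` list.
#' @export
loss_model <- function(lambda, module_members = character(), rho = 0) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("`lambda` must be a single number >= 0", call. = FALSE)
  }
  if (length(rho) != 1L || !is.finite(rho) || rho < 0 || rho > 1) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  module_members <- as.character(module_members)
  if (anyDuplicated(module_members)) {
    stop("duplicate module member ids", call. = FALSE)
  }
  if (rho > 0 && length(module_members) == 0L) {
    stop("`module_members` must be non-empty when `rho` > 0", call. = FALSE)
  }
  structure(list(lambda = lambda, module_members = module_members,
                 rho = rho),
            class = "loss_model")
}

#' Simulate presence/absence profiles by Dollo gene loss on a tree
#'
#' Every OG is present at the root (the LECA convention). Walking each
#' branch of length `L` from the root, an OG is lost with probability
#' `1 - exp(-lambda * L)`; once lost it stays absent in every descendant
#' (Dollo: loss is irreversible, no regain). Module OGs are coupled: on
#' each branch, with probability `rho` a single shared Bernoulli loss
#' indicator applies to all module members (they lose together or not at
#' all on that branch), otherwise each member draws independently. The
#' marginal loss probability per branch is the same in both regimes.
#'
#' Background OGs are labelled `OG00001`, `OG00002`, ...; module rows carry
#' the ids from the loss model and come after the background rows.
#'
#' @param tree an [ape::phylo] species tree (e.g. from [simulate_tree()]).
#' @param n_background number of independent background OGs, >= 0.
#' @param model a [loss_model()].
#' @param seed RNG seed.
#' @param keep_states if `TRUE`, attach the full per-node presence states
#'   as attribute `node_states` (OGs x nodes, node ids in ape numbering)
#'   for auditing the Dollo property.
#' @return a [pa_matrix] with `n_background + length(module_members)` rows
#'   and one column per tree leaf.
#' @export
simulate_gene_loss <- function(tree, n_background, model, seed,
                               keep_states = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "loss_model"))
  if (length(n_background) != 1L || !is.finite(n_background) ||
      n_background < 0) {
    stop("`n_background` must be a single integer >= 0", call. = FALSE)
  }
  n_background <- as.integer(n_background)
  n_tip <- length(tree$tip.label)
  n_mod <- length(model$module_members)
  n_og <- n_background + n_mod
  if (n_og == 0L) stop("no OGs to simulate", call. = FALSE)

  og_ids <- c(if (n_background > 0) sprintf("OG%05d", seq_len(n_background)),
              model$module_members)
  # cladewise order guarantees a parent's edge is visited before its
  # children's edges, so parent states are final when a branch is drawn
  tree <- stats::reorder(tree, "cladewise")
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode
  mod_idx <- if (n_mod > 0) n_background + seq_len(n_mod) else integer()

  states <- with_seed(seed, {
    st <- matrix(FALSE, nrow = n_og, ncol = n_node)
    st[, root] <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      p <- 1 - exp(-model$lambda * tree$edge.length[e])
      lost <- logical(n_og)
      if (n_background > 0) {
        lost[seq_len(n_background)] <- stats::runif(n_background) < p
      }
      if (n_mod > 0) {
        if (stats::runif(1) < model$rho) {
          lost[mod_idx] <- stats::runif(1) < p
        } else {
          lost[mod_idx] <- stats::runif(n_mod) < p
        }
      }
      st[, child] <- st[, parent] & !lost
    }
    st
  })

  m <- matrix(as.integer(states[, seq_len(n_tip), drop = FALSE]),
              nrow = n_og, dimnames = list(og_ids, tree$tip.label))
  out <- pa_matrix(m)
  if (keep_states) {
    attr(out, "node_states") <- states
    attr(out, "tree") <- tree
  }
  out
}
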