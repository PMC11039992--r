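#' Configuration for synthetic EMSA saturation-binding data
#'
#' Describes one simulated titration of a protein (at concentrations in
#' micromolar, vast excess over the labelled RNA probe) against a fixed
#' trace of RNA, under the one-site specific-binding model
#' `y = Bmax * x / (Kd + x)` with additive Gaussian quantification noise.
#' The default concentration series spans the 0.25-25 uM range typical of
#' RRM-snRNA titrations.
#'
#' @param kd_true generating dissociation constant, uM > 0.
#' @param bmax_true generating maximal bound fraction, > 0.
#' @param concentrations protein concentrations, uM, all > 0.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   bound fraction, >= 0.
#' @param n_replicates replicates per concentration, >= 1.
#' @param seed RNG seed.
#' @return a `binding_config` list.
#' @export
binding_config <- function(kd_true, bmax_true = 1,
                           concentrations = c(0.25, 0.5, 1, 2.5, 5, 10, 25),
                           noise_sd = 0.02, n_replicates = 3, seed = 1) {
  if (kd_true <= 0 || bmax_true <= 0) {
    stop("`kd_true` and `bmax_true` must be > 0", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("all concentrations must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  structure(list(kd_true = kd_true, bmax_true = bmax_true,
                 concentrations = sort(concentrations),
                 noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "binding_config")
}

#' Simulate an EMSA titration dataset
#'
#' Draws one record per (concentration, replicate):
#' `y = Bmax * x / (Kd + x) + eps`, `eps ~ Normal(0, noise_sd)`, with `y`
#' clipped to `[0, Bmax]` (phosphorimager band ratios cannot leave that
#' range). Deterministic for a fixed seed.
#'
#' @param config a [binding_config()].
#' @return a data.frame with columns `concentration_uM`, `fraction_bound`,
#'   `replicate`.
#' @export
simulate_emsa <- function(config) {
  stopifnot(inherits(config, "binding_config"))
  x <- rep(config$concentrations, times = config$n_replicates)
  rep_id <- rep(seq_len(config$n_replicates),
                each = length(config$concentrations))
  mu <- predict_fraction_bound(x, config$kd_true, config$bmax_true)
  y <- with_seed(config$seed, {
    mu + stats::rnorm(length(mu), 0, config$noise_sd)
  })
  y <- pmin(pmax(y, 0), config$bmax_true)
  data.frame(concentration_uM = x, fraction_bound = y,
             replicate = sprintf("rep%d", rep_id),
             stringsAsFactors = FALSE)
}
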