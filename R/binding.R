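#' One-site specific-binding model
#'
#' Predicted bound fraction for the hyperbolic one-site model
#' `y = Bmax * x / (Kd + x)`: zero at `x = 0`, half of `Bmax` at `x = Kd`,
#' approaching `Bmax` as `x` grows. This assumes free ligand ~ total ligand
#' (protein in vast excess over the labelled probe), so no depletion
#' correction is applied.
#'
#' @param x protein concentration(s), uM, >= 0.
#' @param kd dissociation constant, uM, > 0.
#' @param bmax maximal bound fraction, > 0.
#' @return predicted bound fraction(s), same length as `x`.
#' @export
predict_fraction_bound <- function(x, kd, bmax) {
  if (length(kd) != 1L || !is.finite(kd) || kd <= 0) {
    stop("`kd` must be a single number > 0", call. = FALSE)
  }
  if (length(bmax) != 1L || !is.finite(bmax) || bmax <= 0) {
    stop("`bmax` must be a single number > 0", call. = FALSE)
  }
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  bmax * x / (kd + x)
}

fit_error <- function(message, diagnostics = list()) {
  stop(structure(class = c("u12kit_fit_error", "error", "condition"),
                 list(message = message, call = NULL,
                      diagnostics = diagnostics)))
}

#' Fit the one-site specific-binding model to titration data
#'
#' Least-squares estimation of `Kd` and `Bmax` from pooled observations
#' (all replicates enter one objective). Parameters are constrained
#' positive via bounded quasi-Newton optimisation (`L-BFGS-B`), then
#' polished by Gauss-Newton iteration to solver precision; standard errors
#' come from the local curvature (Jacobian cross-product) at the optimum.
#' Default initialisation: `bmax0 = max(y)`, `kd0` = the concentration
#' whose observed mean response is nearest `bmax0 / 2`.
#'
#' @param data data.frame with columns `concentration_uM`,
#'   `fraction_bound` and optionally `replicate` (as written by
#'   [simulate_emsa()] or read with [read_binding_table()]).
#' @param init optional numeric `c(kd0, bmax0)` overriding the default
#'   start.
#' @param fix_bmax optional fixed `Bmax`; when given, only `Kd` is
#'   estimated.
#' @param per_replicate if `TRUE`, additionally fit each replicate
#'   separately; the per-replicate estimates are attached as attribute
#'   `replicate_fits`.
#' @return a `kd_estimate`: list with `kd`, `bmax`, `kd_se`, `bmax_se`,
#'   `rss`, `n_obs`, `df_residual`, `converged`, `iterations`.
#' @export
fit_one_site <- function(data, init = NULL, fix_bmax = NULL,
                         per_replicate = FALSE) {
  need <- c("concentration_uM", "fraction_bound")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x <- as.numeric(data$concentration_uM)
  y <- as.numeric(data$fraction_bound)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(x)) < 4L) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  if (max(x) / min(x) < 10) {
    warning("concentration range spans less than 10-fold; ",
            "Kd may be poorly constrained")
  }
  if (stats::sd(y) == 0) {
    fit_error("response is constant across concentrations; Bmax/Kd are unidentifiable",
              diagnostics = list(y_value = y[1L], n_obs = length(y)))
  }

  # default start: saturation from the data, Kd at half-saturation
  ybar <- tapply(y, x, mean)
  xs <- as.numeric(names(ybar))
  bmax0 <- max(y)
  kd0 <- xs[which.min(abs(ybar - bmax0 / 2))]
  if (!is.null(init)) {
    kd0 <- init[[1L]]
    if (length(init) > 1L) bmax0 <- init[[2L]]
    if (kd0 <= 0 || bmax0 <= 0) {
      stop("initial values must be positive", call. = FALSE)
    }
  }

  free_bmax <- is.null(fix_bmax)
  rss_fn <- function(par) {
    b <- if (free_bmax) par[2L] else fix_bmax
    sum((y - b * x / (par[1L] + x))^2)
  }
  par0 <- if (free_bmax) c(kd0, bmax0) else kd0
  lower <- rep(1e-9, length(par0))
  opt <- stats::optim(par0, rss_fn, method = "L-BFGS-B", lower = lower,
                      control = list(factr = 1e4, maxit = 500))

  # Gauss-Newton polish with step halving; exact-data fits reach machine
  # precision here where quasi-Newton stalls near zero residual
  par <- opt$par
  iters <- 0L
  for (it in seq_len(100L)) {
    kd <- par[1L]
    b <- if (free_bmax) par[2L] else fix_bmax
    r <- y - b * x / (kd + x)
    J <- cbind(-b * x / (kd + x)^2,
               if (free_bmax) x / (kd + x))
    step <- tryCatch(solve(crossprod(J), crossprod(J, -r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    rss_old <- sum(r^2)
    lam <- 1
    repeat {
      cand <- pmax(par - lam * as.numeric(step), 1e-12)
      if (rss_fn(cand) <= rss_old || lam < 1e-8) break
      lam <- lam / 2
    }
    moved <- max(abs(cand - par) / pmax(abs(par), 1e-12))
    par <- cand
    iters <- it
    if (moved < 1e-12) break
  }

  kd <- par[1L]
  bmax <- if (free_bmax) par[2L] else fix_bmax
  rss <- rss_fn(par)
  n <- length(y)
  p <- length(par0)
  converged <- opt$convergence == 0 || iters < 100L
  if (!converged) {
    fit_error("one-site fit did not converge",
              diagnostics = list(optim = opt, kd = kd, bmax = bmax,
                                 rss = rss))
  }

  J <- cbind(-bmax * x / (kd + x)^2,
             if (free_bmax) x / (kd + x))
  sigma2 <- if (n > p) rss / (n - p) else NA_real_
  covm <- tryCatch(sigma2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, p, p))
  ses <- sqrt(pmax(diag(covm), 0))

  est <- structure(list(kd = kd, bmax = bmax,
                        kd_se = ses[1L],
                        bmax_se = if (free_bmax) ses[2L] else 0,
                        rss = rss, n_obs = n, df_residual = n - p,
                        converged = TRUE, iterations = iters),
                   class = "kd_estimate")
  if (per_replicate && "replicate" %in% names(data)) {
    reps <- split(data[keep, , drop = FALSE], data$replicate[keep])
    attr(est, "replicate_fits") <-
      lapply(reps, fit_one_site, init = c(kd, bmax), fix_bmax = fix_bmax)
  }
  est
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("One-site specific binding fit (n = %d)\n", x$n_obs))
  cat(sprintf("  Kd   = %.4g +/- %.3g uM\n", x$kd, x$kd_se))
  cat(sprintf("  Bmax = %.4g +/- %.3g\n", x$bmax, x$bmax_se))
  cat(sprintf("  RSS  = %.4g (df = %d)\n", x$rss, x$df_residual))
  invisible(x)
}

#' Ratio of two dissociation constants
#'
#' `a$kd / b$kd`: values above 1 mean `a` binds more weakly (higher Kd)
#' than `b`. The standard error is propagated by the delta method assuming
#' independent fits.
#'
#' @param a,b `kd_estimate` objects from [fit_one_site()].
#' @return a list with `ratio` and `se`.
#' @export
affinity_ratio <- function(a, b) {
  stopifnot(inherits(a, "kd_estimate"), inherits(b, "kd_estimate"))
  ratio <- a$kd / b$kd
  se <- ratio * sqrt((a$kd_se / a$kd)^2 + (b$kd_se / b$kd)^2)
  list(ratio = ratio, se = se)
}

#' Read an EMSA quantification table
#'
#' TSV with columns `concentration_uM`, `fraction_bound`, `replicate`.
#'
#' @param path file path.
#' @return a data.frame suitable for [fit_one_site()].
#' @export
read_binding_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("concentration_uM", "fraction_bound")
  if (!all(need %in% names(tab))) {
    stop("binding table must have columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  }
  tab
}
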