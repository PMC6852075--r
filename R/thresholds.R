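#' Threshold searches over the marginal-effect comparisons
#'
#' Numerical recovery of the parameter-region boundaries at which transmission
#' mode overtakes relatedness (open model), and at which the direct route
#' overtakes the via-relatedness route (closed model). Each search treats the
#' marginal-effect functions as black boxes: an inner maximization over the
#' free parameters locates the most favourable point for the dominance
#' condition, and an outer bisection finds the smallest value of the swept
#' parameter at which the condition is attainable.
#'
#' @name thresholds
NULL

# maximize fn over (lo, hi) without assuming unimodality: coarse grid seed,
# then local refinement around the best grid point
grid_maximize <- function(fn, lo, hi, n_grid = 41L) {
  xs <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(xs, fn, numeric(1))
  i <- which.max(vals)
  bracket <- c(xs[max(1L, i - 1L)], xs[min(n_grid, i + 1L)])
  opt <- stats::optimize(fn, interval = bracket, maximum = TRUE, tol = 1e-10)
  max(opt$objective, vals[i])
}

# largest value of |d x0*/d lambda| - |d x0*/d R| attainable at a given
# lambda, maximizing over R in (0,1) and the fecundity/survival ratio
# fs = f/s in (0, fs_max] (s is fixed at 1; only the ratio matters for the
# sign of the comparison)
dominance_margin <- function(lambda, fs_max) {
  best <- -Inf
  for (fs in exp(seq(log(1e-2), log(fs_max), length.out = 40L))) {
    val <- grid_maximize(function(R) {
      p <- open_params(R = R, lambda = lambda, s = 1, f = fs)
      abs(marginal_effect_transmission(p)) - abs(marginal_effect_relatedness(p))
    }, 1e-9, 1 - 1e-9)
    if (val > best) best <- val
  }
  best
}

#' Smallest horizontal-transmission probability at which transmission mode
#' can dominate
#'
#' Finds, by bisection, the infimum of \code{lambda} for which some
#' combination of relatedness \code{R} in \code{(0, 1)} and
#' fecundity/survival ratio \code{f/s} up to \code{fs_max} makes the marginal
#' effect of transmission mode on the open-model ESS exceed (in magnitude)
#' the marginal effect of relatedness.
#'
#' @param fs_max Upper bound of the \code{f/s} search range.
#' @param tol Bisection tolerance on \code{lambda}.
#' @return The threshold \code{lambda}.
#' @seealso [dominant_factor_open()]
#' @export
dominance_lambda_infimum <- function(fs_max = 1e4, tol = 1e-6) {
  lo <- 0; hi <- 1
  if (dominance_margin(hi, fs_max) <= 0)
    return(NA_real_)  # condition unattainable anywhere
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (dominance_margin(mid, fs_max) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Smallest fecundity/survival ratio at which transmission mode can dominate
#' under full horizontal transmission
#'
#' At \code{lambda = 1}, finds by bisection the infimum of \code{f/s} for
#' which some \code{R} in \code{(0, 1)} makes the transmission-mode marginal
#' effect exceed the relatedness marginal effect in magnitude.
#'
#' @param fs_max Upper bound of the \code{f/s} search range.
#' @param tol Relative bisection tolerance on \code{f/s}.
#' @return The threshold ratio \code{f/s}.
#' @export
dominance_fs_infimum <- function(fs_max = 1e4, tol = 1e-8) {
  margin_at <- function(fs) {
    grid_maximize(function(R) {
      p <- open_params(R = R, lambda = 1, s = 1, f = fs)
      abs(marginal_effect_transmission(p)) - abs(marginal_effect_relatedness(p))
    }, 1e-9, 1 - 1e-9)
  }
  lo <- 1e-2; hi <- fs_max
  if (margin_at(hi) <= 0) return(NA_real_)
  while (hi / lo - 1 > tol) {
    mid <- sqrt(lo * hi)
    if (margin_at(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Smallest horizontal-transmission probability at which the direct route can
#' dominate the via-relatedness route
#'
#' In the closed model, transmission mode acts both directly and via
#' relatedness ([route_decomposition()]). This search finds, by bisection,
#' the infimum of \code{lambda} at which some fecundity/survival ratio up to
#' \code{fs_max} makes the direct effect exceed the indirect effect in
#' magnitude. The comparison is independent of the bottleneck size \code{k}
#' (both routes share the factor \eqn{(k-1)/(A+\lambda(k-1))^2}), which is
#' held at \code{k}.
#'
#' @param fs_max Upper bound of the \code{f/s} search range.
#' @param k Bottleneck size used for the evaluations (\code{>= 2}).
#' @param tol Bisection tolerance on \code{lambda}.
#' @return The threshold \code{lambda}.
#' @export
route_lambda_infimum <- function(fs_max = 1e4, k = 2, tol = 1e-6) {
  margin_at <- function(lambda) {
    best <- -Inf
    for (fs in exp(seq(log(1e-2), log(fs_max), length.out = 40L))) {
      rd <- route_decomposition(closed_params(lambda = lambda, k_h = k,
                                              s = 1, f = fs))
      val <- abs(rd$direct) - abs(rd$indirect)
      if (val > best) best <- val
    }
    best
  }
  lo <- 0; hi <- 1
  if (margin_at(hi) <= 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (margin_at(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
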