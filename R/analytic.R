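#' Fitness of a focal symbiont
#'
#' Expected number of descendant founders of a focal symbiont with cooperation
#' \code{x_i}, living in a host whose symbionts cooperate at mean level
#' \code{x_g}, in a population with mean cooperation \code{x_bar}:
#' \deqn{W = (1-\lambda)\,\frac{1-x_i}{1-x_g}\,
#'           \frac{x_g^s}{\bar{x}^s}\,\frac{x_g^f}{\bar{x}^f}
#'         + \lambda\,\frac{1-x_i}{1-x_g}\,\frac{x_g^s}{\bar{x}^s}.}
#' The first (vertical) component is weighted by both relative host survival
#' and relative host fecundity; the horizontal component only by relative
#' survival. The factor \eqn{(1-x_i)/(1-x_g)} is the focal symbiont's share of
#' within-host growth: cooperation is individually costly. By construction the
#' resident fitness is 1 (\code{x_i = x_g = x_bar}).
#'
#' @param x_i Focal symbiont cooperation, in \code{[0, 1)}.
#' @param x_g Within-host mean cooperation, in \code{[0, 1)}.
#' @param x_bar Population mean cooperation, in \code{[0, 1)}; must be
#'   positive when \code{s > 0} or \code{f > 0}.
#' @param p An [open_params()] object (its \code{R} field is not used here).
#' @return Fitness value (dimensionless, \code{>= 0}).
#' @export
#' @examples
#' p <- open_params(R = 0.5, lambda = 0.3, s = 1, f = 1)
#' symbiont_fitness(0.5, 0.5, 0.5, p)  # resident: 1
symbiont_fitness <- function(x_i, x_g, x_bar, p) {
  stopifnot(inherits(p, "open_params"))
  if (any(c(x_i, x_g, x_bar) >= 1) || any(c(x_i, x_g, x_bar) < 0))
    stop("traits must lie in [0, 1)")
  if (x_bar == 0 && (p$s > 0 || p$f > 0))
    stop("'x_bar' must be > 0 when s > 0 or f > 0")
  share <- (1 - x_i) / (1 - x_g)
  surv <- (x_g^p$s) / (x_bar^p$s)   # 0^0 = 1 in R: s = 0 gives weight 1
  fec <- (x_g^p$f) / (x_bar^p$f)
  (1 - p$lambda) * share * surv * fec + p$lambda * share * surv
}

#' Inclusive fitness effect of cooperation
#'
#' Selection gradient on cooperation from the neighbour-modulated fitness
#' analysis, evaluated in a monomorphic resident population at trait value
#' \code{x}:
#' \deqn{\Delta_{IF}(x) = -\frac{1}{1-x}
#'   + R\left[\frac{s + f(1-\lambda)}{x} + \frac{1}{1-x}\right].}
#' The first term is the within-host competitive cost of cooperating; the
#' second is the host-mediated benefit returned to the whole symbiont group,
#' weighted by whole-group relatedness \code{R}. An interior ESS satisfies
#' \eqn{\Delta_{IF} = 0} with negative slope.
#'
#' @param x Resident trait value, in \code{(0, 1)} (both endpoints are poles).
#' @param p An [open_params()] object.
#' @return The selection gradient (dimensionless). Vectorized over \code{x}.
#' @seealso [ess_open()], [numeric_ess_oracle()]
#' @export
inclusive_fitness_effect <- function(x, p) {
  stopifnot(inherits(p, "open_params"))
  if (any(x <= 0) || any(x >= 1))
    stop("'x' must lie strictly inside (0, 1)")
  A <- benefit_exponent(p$lambda, p$s, p$f)
  -1 / (1 - x) + p$R * (A / x + 1 / (1 - x))
}

# slope of the selection gradient at x; negative slope => local fitness
# maximum, i.e. a convergence-stable candidate ESS
if_gradient_slope <- function(x, p) {
  A <- benefit_exponent(p$lambda, p$s, p$f)
  (p$R - 1) / (1 - x)^2 - p$R * A / x^2
}

ess_solution <- function(x_star, residual, stable) {
  structure(list(x_star = x_star, delta_if_residual = residual,
                 stable = stable),
            class = "ess_solution")
}

#' @export
print.ess_solution <- function(x, ...) {
  cat(sprintf("ESS cooperation x* = %.6g (%s)\n", x$x_star,
              if (isTRUE(x$stable)) "stable" else "unstable"))
  if (is.finite(x$delta_if_residual))
    cat(sprintf("  selection-gradient residual: %.3g\n", x$delta_if_residual))
  invisible(x)
}

#' ESS cooperation in the open model
#'
#' Solves \eqn{\Delta_{IF}(x^*) = 0} in closed form. With
#' \eqn{A = f(1-\lambda) + s},
#' \deqn{x_0^* = \frac{R A}{R A + (1 - R)}.}
#' Clonal symbionts (\code{R = 1}) cooperate fully (\eqn{x^* = 1}); with
#' \code{R = 0} or \code{A = 0} the gradient is negative everywhere and the
#' boundary \eqn{x^* = 0} is returned (selection removes any cooperation).
#'
#' @param p An [open_params()] object.
#' @return An \code{"ess_solution"}: list with \code{x_star} (in
#'   \code{[0, 1]}), \code{delta_if_residual} (gradient at \code{x_star};
#'   \code{NA} for boundary solutions, where the gradient has a pole), and
#'   \code{stable} (negative gradient slope at the solution).
#' @seealso [ess_closed()], [numeric_ess_oracle()]
#' @export
#' @examples
#' ess_open(open_params(R = 0.25, lambda = 0.5, s = 1, f = 2))$x_star  # 0.4
ess_open <- function(p) {
  stopifnot(inherits(p, "open_params"))
  A <- benefit_exponent(p$lambda, p$s, p$f)
  if (p$R == 0 || A == 0)
    return(ess_solution(0, NA_real_, TRUE))
  # denominator written as RA + (1 - R) so the clonal limit R = 1 gives
  # exactly RA/RA = 1 in floating point
  x <- (p$R * A) / (p$R * A + (1 - p$R))
  if (x >= 1)
    return(ess_solution(1, NA_real_, TRUE))
  ess_solution(x, inclusive_fitness_effect(x, p), if_gradient_slope(x, p) <= 0)
}

#' Whole-group relatedness from demography
#'
#' Closed-form whole-group relatedness among symbionts sharing a host,
#' expressed through the transmission mode and the infection bottlenecks:
#' \deqn{R = \frac{k_h (1-\lambda) + \lambda k_v}
#'                {k_h \left(1 + (k_v - 1)\lambda\right)}.}
#' Under full vertical transmission (\code{lambda = 0}) this equals 1 (hosts
#' carry clonal symbiont groups); under full horizontal transmission it equals
#' \code{1/k_h}. With equal bottlenecks \code{k_h = k_v = k} it reduces to
#' \deqn{R = \frac{1}{1 + \lambda (k - 1)}.}
#'
#' @param p A [closed_params()] object.
#' @return Relatedness in \code{(0, 1]}.
#' @export
#' @examples
#' whole_group_relatedness(closed_params(lambda = 1, k_h = 4))    # 1/4
#' whole_group_relatedness(closed_params(lambda = 0, k_h = 10))   # 1
whole_group_relatedness <- function(p) {
  stopifnot(inherits(p, "closed_params"))
  (p$k_h * (1 - p$lambda) + p$lambda * p$k_v) /
    (p$k_h * (1 + (p$k_v - 1) * p$lambda))
}

#' ESS cooperation in the closed model (equal bottlenecks)
#'
#' Substituting the equal-bottleneck relatedness \eqn{R = 1/(1+\lambda(k-1))}
#' into the open-model ESS gives, with \eqn{A = f(1-\lambda)+s},
#' \deqn{x_c^* = \frac{A}{A + (k-1)\lambda}.}
#' This is algebraically identical to
#' \code{ess_open} evaluated at \code{R = whole_group_relatedness(p)}.
#'
#' @param p A [closed_params()] object with \code{k_h == k_v}.
#' @return An \code{"ess_solution"} (see [ess_open()]).
#' @export
#' @examples
#' ess_closed(closed_params(lambda = 1, k_h = 4, s = 1, f = 1))$x_star  # 0.25
ess_closed <- function(p) {
  stopifnot(inherits(p, "closed_params"))
  if (p$k_h != p$k_v)
    stop("ess_closed() requires equal bottlenecks k_h == k_v")
  k <- p$k_h
  A <- benefit_exponent(p$lambda, p$s, p$f)
  if (A == 0)
    return(ess_solution(0, NA_real_, TRUE))
  x <- A / (A + (k - 1) * p$lambda)
  po <- open_params(R = whole_group_relatedness(p), lambda = p$lambda,
                    s = p$s, f = p$f)
  if (x >= 1)
    return(ess_solution(1, NA_real_, TRUE))
  ess_solution(x, inclusive_fitness_effect(x, po), if_gradient_slope(x, po) <= 0)
}

#' Marginal effect of relatedness on the open-model ESS
#'
#' \eqn{\partial x_0^*/\partial R = A / (R(A-1)+1)^2} with
#' \eqn{A = f(1-\lambda)+s}; always nonnegative -- higher relatedness never
#' lowers the ESS level of cooperation.
#'
#' @param p An [open_params()] object.
#' @return The derivative (dimensionless, \code{>= 0}).
#' @export
marginal_effect_relatedness <- function(p) {
  stopifnot(inherits(p, "open_params"))
  A <- benefit_exponent(p$lambda, p$s, p$f)
  A / (p$R * A + (1 - p$R))^2
}

#' Marginal effect of transmission mode on the open-model ESS
#'
#' \eqn{\partial x_0^*/\partial \lambda = -f R(1-R) / (R(A-1)+1)^2}; always
#' nonpositive -- more horizontal transmission never raises the ESS. It
#' vanishes at \code{R = 0} and \code{R = 1}: clonal (or totally unrelated)
#' symbiont groups are insensitive to transmission mode per se.
#'
#' @param p An [open_params()] object.
#' @return The derivative (dimensionless, \code{<= 0}).
#' @export
marginal_effect_transmission <- function(p) {
  stopifnot(inherits(p, "open_params"))
  A <- benefit_exponent(p$lambda, p$s, p$f)
  -p$f * p$R * (1 - p$R) / (p$R * A + (1 - p$R))^2
}

#' Which factor dominates the open-model ESS?
#'
#' Compares the magnitudes of the two marginal effects on \eqn{x_0^*}. Since
#' both share the denominator \eqn{(R(A-1)+1)^2}, transmission mode dominates
#' exactly when \eqn{f R(1-R) > f(1-\lambda) + s}.
#'
#' @param p An [open_params()] object.
#' @param tie_tol Relative tolerance below which the two magnitudes are
#'   reported as a tie (the boundary curve is itself of interest).
#' @return One of \code{"relatedness"}, \code{"transmission"}, \code{"tie"}.
#' @export
#' @examples
#' dominant_factor_open(open_params(R = 0.5, lambda = 0.9, s = 0.1, f = 10))
dominant_factor_open <- function(p, tie_tol = 1e-12) {
  stopifnot(inherits(p, "open_params"))
  m_r <- abs(marginal_effect_relatedness(p))
  m_t <- abs(marginal_effect_transmission(p))
  if (abs(m_t - m_r) <= tie_tol * max(m_r, m_t, 1)) return("tie")
  if (m_t > m_r) "transmission" else "relatedness"
}

#' Decompose the effect of transmission mode in the closed model
#'
#' In the closed model transmission mode acts on the ESS through two routes:
#' directly (holding relatedness fixed) and indirectly via its effect on
#' relatedness. With equal bottlenecks and \eqn{A = f(1-\lambda)+s}:
#' \describe{
#'   \item{total}{\eqn{\partial x_c^*/\partial\lambda =
#'     -(k-1)(f+s)/(A+\lambda(k-1))^2}}
#'   \item{direct}{\eqn{\partial x_0^*/\partial\lambda} evaluated at
#'     \eqn{R = 1/(1+\lambda(k-1))}, equal to
#'     \eqn{-f\lambda(k-1)/(A+\lambda(k-1))^2}}
#'   \item{indirect}{total \eqn{-} direct (the via-relatedness route)}
#'   \item{ratio}{\eqn{|indirect|/|direct| = A/(f\lambda)}; \code{Inf} when
#'     the direct route vanishes (\code{lambda = 0} or \code{f = 0})}
#' }
#'
#' @param p A [closed_params()] object with \code{k_h == k_v >= 2}.
#' @return A list of class \code{"route_decomposition"} with fields
#'   \code{total}, \code{direct}, \code{indirect}, \code{ratio}.
#' @export
#' @examples
#' route_decomposition(closed_params(lambda = 0.5, k_h = 4, s = 1, f = 1))
route_decomposition <- function(p) {
  stopifnot(inherits(p, "closed_params"))
  if (p$k_h != p$k_v)
    stop("route_decomposition() requires equal bottlenecks k_h == k_v")
  k <- p$k_h
  if (k < 2)
    stop("route_decomposition() requires k >= 2 (k = 1 nullifies both routes)")
  A <- benefit_exponent(p$lambda, p$s, p$f)
  m <- p$lambda * (k - 1)
  denom <- (A + m)^2
  total <- -(k - 1) * (p$f + p$s) / denom
  direct <- -p$f * p$lambda * (k - 1) / denom
  indirect <- total - direct
  ratio <- if (direct == 0) Inf else abs(indirect) / abs(direct)
  structure(list(total = total, direct = direct, indirect = indirect,
                 ratio = ratio),
            class = "route_decomposition")
}

#' @export
print.route_decomposition <- function(x, ...) {
  cat(sprintf("d x_c*/d lambda (total):    %.6g\n", x$total))
  cat(sprintf("  direct route:             %.6g\n", x$direct))
  cat(sprintf("  via relatedness:          %.6g\n", x$indirect))
  cat(sprintf("  |indirect| / |direct|:    %.6g\n", x$ratio))
  invisible(x)
}

#' Numeric ESS oracle from finite differences
#'
#' Independent check of the closed-form ESS: the selection gradient is
#' assembled purely from central finite differences of [symbiont_fitness()]
#' in \code{x_i} and \code{x_g} (the neighbour-modulated recipe
#' \eqn{\partial W/\partial x_i + R\,\partial W/\partial x_g}), and its root
#' is located by bracketed bisection on \code{(eps, 1 - eps)}. When the
#' gradient does not change sign the nearer boundary is returned (0 when the
#' gradient is negative throughout, \code{1 - eps} when positive).
#'
#' @param p An [open_params()] object.
#' @param tol Bisection interval tolerance.
#' @param h Finite-difference step.
#' @param eps Distance from the trait-space boundaries.
#' @return The root (trait value in \code{[0, 1]}).
#' @export
numeric_ess_oracle <- function(p, tol = 1e-10, h = 1e-6, eps = 1e-5) {
  stopifnot(inherits(p, "open_params"))
  if (eps <= h) stop("'eps' must exceed the finite-difference step 'h'")
  grad <- function(x) {
    dWdxi <- (symbiont_fitness(x + h, x, x, p) -
                symbiont_fitness(x - h, x, x, p)) / (2 * h)
    dWdxg <- (symbiont_fitness(x, x + h, x, p) -
                symbiont_fitness(x, x - h, x, p)) / (2 * h)
    dWdxi + p$R * dWdxg
  }
  lo <- eps
  hi <- 1 - eps
  glo <- grad(lo)
  ghi <- grad(hi)
  if (glo <= 0 && ghi <= 0) return(0)
  if (glo >= 0 && ghi >= 0) return(hi)
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    gm <- grad(mid)
    if (gm == 0) return(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid; glo <- gm
    } else {
      hi <- mid
    }
    if (hi - lo < tol) break
  }
  root <- (lo + hi) / 2
  if (abs(grad(root)) > 1e-3)
    stop("numeric_ess_oracle: residual gradient too large at located root")
  root
}
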