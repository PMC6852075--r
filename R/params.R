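#' Parameters of the open analytical model
#'
#' Bundles the parameters of the open model of symbiont cooperation, in which
#' whole-group relatedness \code{R} is a free parameter alongside the
#' transmission mode \code{lambda}. Host survival and fecundity respond to the
#' within-host mean cooperation \code{x_g} as power laws \code{x_g^s} and
#' \code{x_g^f} (with the convention \code{0^0 = 1}, so an exponent of zero
#' means the corresponding host component is insensitive to cooperation).
#'
#' @param R Whole-group relatedness coefficient, in \code{[0, 1]}.
#' @param lambda Probability that a new host is founded horizontally,
#'   in \code{[0, 1]}; \code{1 - lambda} is the probability of vertical
#'   founding from the parent host.
#' @param s Host-survival exponent, \code{>= 0}.
#' @param f Host-fecundity exponent, \code{>= 0}.
#'
#' @return An object of class \code{"open_params"}: a named list with fields
#'   \code{R}, \code{lambda}, \code{s}, \code{f}.
#' @seealso [closed_params()], [ess_open()]
#' @export
#' @examples
#' p <- open_params(R = 0.5, lambda = 0.25, s = 1, f = 1)
#' ess_open(p)$x_star
open_params <- function(R, lambda, s, f) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(f), length(f) == 1L, is.finite(f))
  if (R < 0 || R > 1) stop("'R' must lie in [0, 1]")
  if (lambda < 0 || lambda > 1) stop("'lambda' must lie in [0, 1]")
  if (s < 0) stop("'s' must be >= 0")
  if (f < 0) stop("'f' must be >= 0")
  structure(list(R = R, lambda = lambda, s = s, f = f),
            class = "open_params")
}

#' Parameters of the demographically closed model
#'
#' In the closed model, whole-group relatedness is no longer free: it is
#' determined by the transmission mode \code{lambda} and by the infection
#' bottleneck sizes -- the number of founding symbionts a new host receives
#' when founded horizontally (\code{k_h}) or vertically (\code{k_v}).
#'
#' @param lambda Probability of horizontal founding, in \code{[0, 1]}.
#' @param k_h Horizontal bottleneck size (integer \code{>= 1}).
#' @param k_v Vertical bottleneck size (integer \code{>= 1}).
#' @param s Host-survival exponent, \code{>= 0}.
#' @param f Host-fecundity exponent, \code{>= 0}.
#'
#' @return An object of class \code{"closed_params"}: a named list with fields
#'   \code{lambda}, \code{k_h}, \code{k_v}, \code{s}, \code{f}.
#' @seealso [whole_group_relatedness()], [ess_closed()]
#' @export
#' @examples
#' whole_group_relatedness(closed_params(lambda = 0.5, k_h = 2, k_v = 10))
closed_params <- function(lambda, k_h, k_v = k_h, s = 1, f = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(k_h), length(k_h) == 1L, is.finite(k_h),
            is.numeric(k_v), length(k_v) == 1L, is.finite(k_v),
            is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(f), length(f) == 1L, is.finite(f))
  if (lambda < 0 || lambda > 1) stop("'lambda' must lie in [0, 1]")
  if (k_h < 1 || k_h != round(k_h)) stop("'k_h' must be an integer >= 1")
  if (k_v < 1 || k_v != round(k_v)) stop("'k_v' must be an integer >= 1")
  if (s < 0) stop("'s' must be >= 0")
  if (f < 0) stop("'f' must be >= 0")
  structure(list(lambda = lambda, k_h = as.integer(k_h),
                 k_v = as.integer(k_v), s = s, f = f),
            class = "closed_params")
}

# benefit exponent A = f(1 - lambda) + s, shared by the open and closed ESS
benefit_exponent <- function(lambda, s, f) f * (1 - lambda) + s
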