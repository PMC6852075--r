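#' Realized whole-group relatedness from trait values
#'
#' Regression (covariance) estimator of whole-group relatedness measured at
#' the cooperation trait itself: over all symbionts,
#' \deqn{\hat{R} = \mathrm{cov}(x_i, x_{g(i)}) / \mathrm{var}(x_i),}
#' where \eqn{x_{g(i)}} is the mean trait of the focal symbiont's host group
#' \emph{including} the focal symbiont. For random assignment of unrelated
#' symbionts into groups of size \code{k} the expectation is \code{1/k}; for
#' internally clonal hosts it is 1.
#'
#' @param traits Numeric matrix, hosts in rows, symbionts in columns.
#' @return The relatedness estimate, or \code{NA} when the population is
#'   monomorphic (zero trait variance).
#' @export
#' @examples
#' m <- matrix(rep(c(0.2, 0.8), each = 3), nrow = 2, byrow = TRUE)
#' realized_relatedness(m)  # internally clonal hosts: 1
realized_relatedness <- function(traits) {
  stopifnot(is.matrix(traits), is.numeric(traits))
  x <- as.vector(traits)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(NA_real_)
  xg <- rep(rowMeans(traits), times = ncol(traits))
  stats::cov(x, xg) / v
}

#' Realized whole-group relatedness from neutral lineage tags
#'
#' Marker-based counterpart of [realized_relatedness()]: each founder lineage
#' is an allele at a neutral locus, and the whole-group regression estimator
#' is pooled over alleles,
#' \eqn{\hat{R} = \sum_a \mathrm{cov}(z_i^a, z_{g(i)}^a) /
#'      \sum_a \mathrm{var}(z_i^a)},
#' with \eqn{z_i^a} the indicator that symbiont \code{i} carries allele
#' \code{a}.
#'
#' @param tags Integer matrix of lineage tags, hosts in rows.
#' @return The relatedness estimate, or \code{NA} when a single lineage has
#'   fixed.
#' @export
marker_relatedness <- function(tags) {
  stopifnot(is.matrix(tags))
  alleles <- unique(as.vector(tags))
  if (length(alleles) < 2L) return(NA_real_)
  num <- 0
  den <- 0
  k <- ncol(tags)
  for (a in alleles) {
    z <- (tags == a) * 1
    zv <- as.vector(z)
    zg <- rep(rowMeans(z), times = k)
    num <- num + stats::cov(zv, zg)
    den <- den + stats::var(zv)
  }
  num / den
}

#' Count modes of a trait distribution
#'
#' Gaussian kernel density estimate of the trait sample on
#' \code{[0, x_max]} (Silverman's rule-of-thumb bandwidth with a floor),
#' followed by a peak scan: local maxima whose density is below 5\% of the
#' global maximum are discarded, and adjacent maxima are merged unless
#' separated by a valley falling below 50\% of the lower of the two peaks.
#' This operationalizes "bimodal trait distribution" for branching calls;
#' it is deterministic given the sample and bandwidth rule.
#'
#' @param x Numeric sample of trait values (length \code{>= 50}).
#' @param x_max Upper end of the trait domain.
#' @param bw_floor Lower bound on the bandwidth (guards against degenerate
#'   near-monomorphic samples).
#' @param min_height_frac Peaks below this fraction of the tallest peak are
#'   ignored.
#' @param valley_frac Two peaks are merged unless the density between them
#'   dips below this fraction of the lower peak.
#' @param n_grid Number of density evaluation points.
#' @return List with \code{n_modes}, \code{modes} (trait locations),
#'   \code{masses} (fraction of the sample nearest each mode, split at the
#'   inter-mode valleys), and \code{bandwidth}.
#' @export
#' @examples
#' set.seed(1)
#' detect_modes(c(rnorm(500, 0.2, 0.02), rnorm(500, 0.6, 0.02)))$n_modes  # 2
detect_modes <- function(x, x_max = 1 - 1e-6, bw_floor = 0.005,
                         min_height_frac = 0.05, valley_frac = 0.5,
                         n_grid = 512L) {
  stopifnot(is.numeric(x))
  if (length(x) < 50L)
    stop("detect_modes() needs a sample of at least 50 values")
  bw <- max(stats::bw.nrd0(x), bw_floor)
  d <- stats::density(x, bw = bw, from = 0, to = x_max, n = n_grid)
  y <- d$y
  n <- length(y)
  # local maxima, boundaries included
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (i == n) -Inf else y[i + 1L]
    y[i] >= left && y[i] > right || (y[i] > left && y[i] >= right)
  }, logical(1))
  peaks <- which(is_peak & y >= min_height_frac * max(y))
  # merge adjacent peaks that lack a deep enough valley between them
  if (length(peaks) > 1L) {
    keep <- peaks[1L]
    for (pk in peaks[-1L]) {
      prev <- keep[length(keep)]
      valley <- min(y[prev:pk])
      if (valley < valley_frac * min(y[prev], y[pk])) {
        keep <- c(keep, pk)
      } else if (y[pk] > y[prev]) {
        keep[length(keep)] <- pk  # same cluster: keep the taller summit
      }
    }
    peaks <- keep
  }
  modes <- d$x[peaks]
  masses <- rep(1, length(peaks))
  if (length(peaks) > 1L) {
    cuts <- vapply(seq_len(length(peaks) - 1L), function(j) {
      seg <- peaks[j]:peaks[j + 1L]
      d$x[seg[which.min(y[seg])]]
    }, numeric(1))
    bins <- findInterval(x, cuts) + 1L
    masses <- tabulate(bins, nbins = length(peaks)) / length(x)
  }
  list(n_modes = length(peaks), modes = modes, masses = masses,
       bandwidth = bw)
}

#' Classify a simulation run as branched or not
#'
#' A run counts as branched when its trait distribution holds at least two
#' modes, each containing at least \code{min_mass} of the symbionts, for at
#' least \code{min_persistence} consecutive recorded snapshots, with the
#' qualifying streak reaching into the final half of the run. The
#' persistence and mass requirements distinguish true evolutionary branching
#' from transient mutation--selection polymorphism (recurrent low-cooperation
#' mutants under weak bottlenecking).
#'
#' @param sim A \code{"symcoop_sim"} run with snapshots
#'   (\code{run_simulation(..., keep_snapshots = TRUE)}).
#' @param min_persistence Minimum number of consecutive qualifying recorded
#'   snapshots.
#' @param min_mass Minimum fraction of symbionts per mode.
#' @param ... Passed to [detect_modes()].
#' @return A \code{"branching_call"}: list with \code{branched},
#'   \code{n_modes_final}, \code{first_branch_generation} (\code{NA} when not
#'   branched), and \code{persistence} (length of the longest qualifying
#'   streak).
#' @export
classify_branching <- function(sim, min_persistence = 5L, min_mass = 0.05,
                               ...) {
  stopifnot(inherits(sim, "symcoop_sim"))
  if (is.null(sim$snapshots))
    stop("classify_branching() needs snapshots; rerun with keep_snapshots = TRUE")
  snaps <- sim$snapshots
  gens <- as.numeric(names(snaps))
  n_rec <- length(snaps)
  if (n_rec < 4L * min_persistence)
    stop("trajectory too short: need at least 4 * min_persistence recorded snapshots")
  qual <- logical(n_rec)
  n_modes_seq <- integer(n_rec)
  for (i in seq_len(n_rec)) {
    md <- detect_modes(as.vector(snaps[[i]]), x_max = sim$config$x_max, ...)
    n_modes_seq[i] <- md$n_modes
    qual[i] <- md$n_modes >= 2L && sum(md$masses >= min_mass) >= 2L
  }
  half_gen <- sim$config$n_generations / 2
  # maximal runs of qualifying snapshots
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- 0L
  first_gen <- NA_real_
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    len <- r$lengths[j]
    if (len >= min_persistence && gens[ends[j]] >= half_gen) {
      if (is.na(first_gen)) first_gen <- gens[starts[j]]
      best <- max(best, len)
    }
  }
  structure(list(branched = best >= min_persistence,
                 n_modes_final = n_modes_seq[n_rec],
                 first_branch_generation = first_gen,
                 persistence = best),
            class = "branching_call")
}

#' @export
print.branching_call <- function(x, ...) {
  if (x$branched) {
    cat(sprintf(
      "branched: %d final mode(s), first qualifying streak at generation %g (persistence %d)\n",
      x$n_modes_final, x$first_branch_generation, x$persistence))
  } else {
    cat(sprintf("not branched (%d final mode(s))\n", x$n_modes_final))
  }
  invisible(x)
}

#' Observed versus demographically predicted relatedness
#'
#' Compares the time-averaged realized whole-group relatedness of a run
#' (trait-based estimator, burn-in excluded) with the closed-model pedigree
#' prediction from the run's transmission mode and bottleneck size. In
#' monomorphic regimes the two agree closely; after evolutionary branching
#' the observed relatedness exceeds the prediction, because cooperative and
#' defecting lineages assort differently across hosts.
#'
#' @param sim A \code{"symcoop_sim"} run.
#' @param p Optional [closed_params()]; defaults to the run's own
#'   \code{lambda} and \code{k}.
#' @param burnin_frac Fraction of generations discarded before averaging.
#' @return List with \code{predicted}, \code{observed}, \code{difference}
#'   (observed minus predicted).
#' @export
compare_relatedness <- function(sim, p = NULL, burnin_frac = 0.25) {
  stopifnot(inherits(sim, "symcoop_sim"))
  cfg <- sim$config
  if (is.null(p))
    p <- closed_params(lambda = cfg$lambda, k_h = cfg$k, k_v = cfg$k,
                       s = cfg$s, f = cfg$f)
  predicted <- whole_group_relatedness(p)
  s <- sim$summary
  keep <- s$generation >= burnin_frac * cfg$n_generations &
    !is.na(s$realized_R)
  if (!any(keep))
    stop("no defined realized relatedness values after burn-in")
  observed <- mean(s$realized_R[keep])
  list(predicted = predicted, observed = observed,
       difference = observed - predicted)
}
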