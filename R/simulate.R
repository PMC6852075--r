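#' Configuration of an individual-based simulation run
#'
#' Fixes every ingredient of one simulation of the host--symbiont life cycle:
#' a constant number of hosts, each carrying exactly \code{k} symbionts; host
#' survival and fecundity scaling with the within-host mean cooperation as
#' \code{x_g^s} and \code{x_g^f}; each offspring host founded horizontally
#' (probability \code{lambda}, founders drawn from the survival-weighted
#' global symbiont pool) or vertically (founders drawn from one
#' fitness-weighted parent host); and founder mutation with a reflected
#' Gaussian kernel.
#'
#' @param n_hosts Number of hosts (integer \code{>= 2}).
#' @param k Symbionts per host -- the bottleneck size (integer \code{>= 1}).
#' @param lambda Probability each new host is founded horizontally.
#' @param s Host-survival exponent.
#' @param f Host-fecundity exponent.
#' @param mu Mutation probability per founding symbiont.
#' @param sigma Mutation step standard deviation (trait units).
#' @param x_init Initial trait value for every symbiont, in
#'   \code{[0, x_max]}.
#' @param x_max Upper trait clamp, strictly below 1 (the within-host share
#'   \code{(1-x_i)/(1-x_g)} is singular at 1).
#' @param n_generations Number of generations to simulate.
#' @param record_every Interval (in generations) between recorded summaries.
#' @param seed RNG seed (integer).
#' @param track_tags Carry neutral integer lineage tags alongside the trait
#'   (used for marker-based relatedness estimates).
#' @return An object of class \code{"sim_config"}.
#' @seealso [run_simulation()]
#' @export
sim_config <- function(n_hosts = 1000L, k = 4L, lambda = 1, s = 1, f = 1,
                       mu = 0.01, sigma = 0.02, x_init = 0.5,
                       x_max = 1 - 1e-6, n_generations = 2500L,
                       record_every = 25L, seed = 1L, track_tags = FALSE) {
  stopifnot(n_hosts >= 2, n_hosts == round(n_hosts),
            k >= 1, k == round(k),
            lambda >= 0, lambda <= 1, s >= 0, f >= 0,
            mu >= 0, mu <= 1, sigma >= 0,
            x_max > 0, x_max < 1,
            n_generations >= 1, n_generations == round(n_generations),
            record_every >= 1, record_every == round(record_every),
            is.finite(seed))
  if (x_init < 0 || x_init > x_max)
    stop("'x_init' must lie in [0, x_max]")
  structure(list(n_hosts = as.integer(n_hosts), k = as.integer(k),
                 lambda = lambda, s = s, f = f, mu = mu, sigma = sigma,
                 x_init = x_init, x_max = x_max,
                 n_generations = as.integer(n_generations),
                 record_every = as.integer(record_every),
                 seed = as.integer(seed), track_tags = isTRUE(track_tags)),
            class = "sim_config")
}

#' Initial population state
#'
#' @param cfg A [sim_config()] object.
#' @return A \code{"population_state"}: list with \code{traits} (an
#'   \code{n_hosts x k} matrix, every entry \code{x_init}),
#'   \code{generation = 0}, and, when tags are tracked, \code{tags} (unique
#'   integer lineage labels).
#' @export
initialize_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  traits <- matrix(cfg$x_init, nrow = cfg$n_hosts, ncol = cfg$k)
  st <- list(traits = traits, generation = 0L)
  if (cfg$track_tags)
    st$tags <- matrix(seq_len(cfg$n_hosts * cfg$k),
                      nrow = cfg$n_hosts, ncol = cfg$k)
  structure(st, class = "population_state")
}

# reflect values into [0, upper] (period-2*upper folding; mutation steps are
# small so a single fold is typical, the modulo handles any excursion)
reflect_into <- function(x, upper) {
  y <- x %% (2 * upper)
  ifelse(y > upper, 2 * upper - y, y)
}

# draw one founder index per row of a weight matrix (rows = offspring hosts,
# cols = parent-host symbionts), sampling proportional to the row weights
sample_row_indices <- function(w) {
  cw <- w
  for (j in seq_len(ncol(w))[-1L]) cw[, j] <- cw[, j - 1L] + w[, j]
  tot <- cw[, ncol(cw)]
  u <- stats::runif(nrow(w)) * tot
  rowSums(u > cw) + 1L
}

#' Advance the population one generation
#'
#' One pass of the life cycle: (1) each host's within-host mean cooperation
#' \code{x_g} sets its survival weight \code{x_g^s} and fecundity weight
#' \code{x_g^f} (\code{0^0 = 1}); (2) each of the \code{n_hosts} offspring
#' hosts is founded horizontally with probability \code{lambda}, otherwise
#' vertically; (3) a vertical host picks one parent host with probability
#' proportional to \code{survival * fecundity} and draws \code{k} founders
#' with replacement from that host's symbionts with within-host weight
#' \code{1 - x_i}; (4) a horizontal host draws \code{k} founders with
#' replacement from the global pool, symbiont \code{i} in host \code{h}
#' weighted by \code{survival_h * (1 - x_i)/(1 - x_g(h))}; (5) each founder
#' mutates with probability \code{mu} by a Normal(0, \code{sigma}) step
#' reflected into \code{[0, x_max]}. Selection is soft: the number of hosts
#' and symbionts per host is constant.
#'
#' If every weight in a required sampling pool is zero (e.g. all
#' \code{x_g = 0} with \code{s > 0}), that pool falls back to uniform
#' sampling with a warning.
#'
#' Uses the current RNG stream; seed control lives in [run_simulation()].
#'
#' @param state A \code{"population_state"}.
#' @param cfg A [sim_config()] object.
#' @return The next \code{"population_state"}, with an added attribute
#'   \code{frac_horizontal} (realized fraction of hosts founded
#'   horizontally).
#' @export
advance_generation <- function(state, cfg) {
  stopifnot(inherits(state, "population_state"), inherits(cfg, "sim_config"))
  traits <- state$traits
  n <- nrow(traits)
  k <- ncol(traits)
  x_g <- rowMeans(traits)
  surv <- x_g^cfg$s
  fec <- x_g^cfg$f

  horiz <- stats::runif(n) < cfg$lambda
  n_h <- sum(horiz)
  n_v <- n - n_h

  new_traits <- matrix(NA_real_, nrow = n, ncol = k)
  tags <- state$tags
  new_tags <- if (!is.null(tags)) matrix(NA_integer_, nrow = n, ncol = k)

  if (n_v > 0L) {
    w_parent <- surv * fec
    if (sum(w_parent) == 0) {
      warning("all vertical parent-host weights are zero; sampling uniformly")
      w_parent <- rep(1, n)
    }
    vert_rows <- which(!horiz)
    parents <- sample.int(n, n_v, replace = TRUE, prob = w_parent)
    w_within <- 1 - traits[parents, , drop = FALSE]
    zero_rows <- rowSums(w_within) == 0
    if (any(zero_rows)) {
      warning("all within-host founder weights are zero in some hosts; ",
              "sampling uniformly there")
      w_within[zero_rows, ] <- 1
    }
    for (d in seq_len(k)) {
      idx <- sample_row_indices(w_within)
      sel <- cbind(parents, idx)
      new_traits[vert_rows, d] <- traits[sel]
      if (!is.null(tags)) new_tags[vert_rows, d] <- tags[sel]
    }
  }

  if (n_h > 0L) {
    # per-symbiont global weight: S_h * (1 - x_i) / (1 - x_g(h))
    w_pool <- as.vector(surv / (1 - x_g) * (1 - traits))
    if (sum(w_pool) == 0) {
      warning("all horizontal pool weights are zero; sampling uniformly")
      w_pool <- rep(1, n * k)
    }
    picks <- sample.int(n * k, n_h * k, replace = TRUE, prob = w_pool)
    new_traits[which(horiz), ] <- traits[picks]
    if (!is.null(tags)) new_tags[which(horiz), ] <- tags[picks]
  }

  if (cfg$mu > 0 && cfg$sigma > 0) {
    hit <- stats::runif(n * k) < cfg$mu
    if (any(hit)) {
      new_traits[hit] <- reflect_into(
        new_traits[hit] + stats::rnorm(sum(hit), 0, cfg$sigma), cfg$x_max)
    }
  }
  new_traits[new_traits > cfg$x_max] <- cfg$x_max

  out <- list(traits = new_traits, generation = state$generation + 1L)
  if (!is.null(tags)) out$tags <- new_tags
  out <- structure(out, class = "population_state")
  attr(out, "frac_horizontal") <- n_h / n
  out
}

#' Run an individual-based simulation
#'
#' Iterates [advance_generation()] for \code{cfg$n_generations} generations,
#' recording a per-generation summary every \code{cfg$record_every}
#' generations (and at generation 0). The RNG is seeded from
#' \code{cfg$seed}, so identical configurations yield identical
#' trajectories.
#'
#' @param cfg A [sim_config()] object.
#' @param keep_snapshots Keep the full trait matrix at every recorded
#'   generation (needed for mode detection and branching classification).
#' @return An object of class \code{"symcoop_sim"}: list with
#'   \describe{
#'     \item{summary}{data frame with columns \code{generation},
#'       \code{mean_x}, \code{var_x}, \code{realized_R} (\code{NA} when the
#'       population is monomorphic), \code{n_modes},
#'       \code{frac_horizontal}.}
#'     \item{snapshots}{when requested, a named list of trait matrices keyed
#'       by generation.}
#'     \item{config}{the resolved configuration.}
#'   }
#' @export
#' @examples
#' sim <- run_simulation(sim_config(n_hosts = 50, k = 2, lambda = 0.5,
#'                                  n_generations = 50, record_every = 10,
#'                                  seed = 42))
#' head(sim$summary)
run_simulation <- function(cfg, keep_snapshots = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  state <- initialize_population(cfg)
  rec_gens <- seq(0L, cfg$n_generations, by = cfg$record_every)
  rows <- vector("list", length(rec_gens))
  snaps <- if (keep_snapshots) vector("list", length(rec_gens))
  r <- 1L
  summarize <- function(state, frac_h) {
    x <- as.vector(state$traits)
    v <- stats::var(x)
    data.frame(
      generation = state$generation,
      mean_x = mean(x),
      var_x = v,
      realized_R = if (v > 0) realized_relatedness(state$traits) else NA_real_,
      n_modes = if (length(x) >= 50L)
        detect_modes(x, x_max = cfg$x_max)$n_modes else NA_integer_,
      frac_horizontal = frac_h)
  }
  rows[[r]] <- summarize(state, NA_real_)
  if (keep_snapshots) snaps[[r]] <- state$traits
  r <- r + 1L
  for (g in seq_len(cfg$n_generations)) {
    state <- advance_generation(state, cfg)
    if (g %% cfg$record_every == 0L) {
      rows[[r]] <- summarize(state, attr(state, "frac_horizontal"))
      if (keep_snapshots) snaps[[r]] <- state$traits
      r <- r + 1L
    }
  }
  out <- list(summary = do.call(rbind, rows), config = cfg,
              final_state = state)
  if (keep_snapshots) {
    names(snaps) <- rec_gens
    out$snapshots <- snaps
  }
  structure(out, class = "symcoop_sim")
}

#' @export
print.symcoop_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Individual-based run: %d hosts x %d symbionts, lambda = %g, s = %g, f = %g\n",
    cfg$n_hosts, cfg$k, cfg$lambda, cfg$s, cfg$f))
  cat(sprintf("  %d generations, seed %d; %d recorded summaries\n",
              cfg$n_generations, cfg$seed, nrow(x$summary)))
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("  final mean cooperation %.4f (variance %.2g, %d mode%s)\n",
              last$mean_x, last$var_x, last$n_modes,
              if (last$n_modes == 1) "" else "s"))
  invisible(x)
}

#' Time-averaged mean cooperation over the monomorphic plateau
#'
#' Averages \code{mean_x} over recorded summaries after a burn-in fraction,
#' restricted to summaries before the first detected branching event (if
#' any); used to compare simulated quasi-equilibria against the analytical
#' ESS.
#'
#' @param sim A \code{"symcoop_sim"} result (snapshots required only if a
#'   branching call is requested).
#' @param burnin_frac Fraction of generations discarded as transient.
#' @param before_branching Exclude summaries at or after the first qualifying
#'   branching streak (requires snapshots; silently skipped without them).
#' @param min_persistence Passed to [classify_branching()].
#' @return The time-averaged mean trait (scalar).
#' @export
plateau_mean <- function(sim, burnin_frac = 0.25, before_branching = TRUE,
                         min_persistence = 5L) {
  stopifnot(inherits(sim, "symcoop_sim"))
  s <- sim$summary
  cutoff <- burnin_frac * sim$config$n_generations
  keep <- s$generation >= cutoff
  if (before_branching && !is.null(sim$snapshots)) {
    bc <- classify_branching(sim, min_persistence = min_persistence)
    if (bc$branched)
      keep <- keep & s$generation < bc$first_branch_generation
  }
  if (!any(keep))
    stop("no summaries left after burn-in/branching exclusion")
  mean(s$mean_x[keep])
}
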