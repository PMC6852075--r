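#' Specify a parameter sweep
#'
#' Builds the full factorial grid over the supplied parameter vectors for one
#' of five sweep modes: open-model ESS surfaces (\code{"ess_open"}),
#' closed-model ESS curves (\code{"ess_closed"}), marginal-effect dominance
#' maps (\code{"dominance"}), route-decomposition maps (\code{"routes"}), or
#' replicated individual-based runs (\code{"simulate"}).
#'
#' @param mode Sweep mode (see above).
#' @param R Relatedness grid (open-model modes).
#' @param lambda Transmission-mode grid.
#' @param s,f Exponent grids.
#' @param k Equal-bottleneck grid (closed-model and simulate modes).
#' @param replicates Seeds per cell (simulate mode).
#' @param base_seed Base seed from which per-cell seeds are derived
#'   (simulate mode).
#' @param sim Named list of [sim_config()] overrides applied to every
#'   simulate-mode cell (e.g. \code{n_hosts}, \code{n_generations}).
#' @return A \code{"sweep_spec"}: list with the expanded \code{grid} data
#'   frame and the sweep settings.
#' @export
sweep_spec <- function(mode = c("ess_open", "ess_closed", "dominance",
                                "routes", "simulate"),
                       R = NA_real_, lambda = NA_real_, s = 1, f = 1,
                       k = NA_integer_, replicates = 1L, base_seed = 1L,
                       sim = list()) {
  mode <- match.arg(mode)
  open_mode <- mode %in% c("ess_open", "dominance")
  if (open_mode && anyNA(R)) stop("mode '", mode, "' needs an R grid")
  if (!open_mode && anyNA(k)) stop("mode '", mode, "' needs a k grid")
  if (anyNA(lambda)) stop("a lambda grid is required")
  stopifnot(replicates >= 1, replicates == round(replicates))
  grid <- if (open_mode) {
    expand.grid(R = R, lam = lambda, s = s, f = f,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(k = k, lam = lambda, s = s, f = f,
                KEEP.OUT.ATTRS = FALSE)
  }
  if (nrow(grid) == 0L) stop("empty parameter grid")
  structure(list(mode = mode, grid = grid,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), sim = sim),
            class = "sweep_spec")
}

sweep_columns <- c("mode", "R", "lam", "s", "f", "k_h", "k_v", "k", "seed",
                   "x_star", "stable", "dominant_factor", "route_ratio",
                   "mean_x", "var_x", "realized_R_obs", "realized_R_pred",
                   "branched", "first_branch_generation", "error")

empty_sweep_row <- function(mode) {
  data.frame(mode = mode, R = NA_real_, lam = NA_real_, s = NA_real_,
             f = NA_real_, k_h = NA_integer_, k_v = NA_integer_,
             k = NA_integer_, seed = NA_integer_, x_star = NA_real_,
             stable = NA, dominant_factor = NA_character_,
             route_ratio = NA_real_, mean_x = NA_real_, var_x = NA_real_,
             realized_R_obs = NA_real_, realized_R_pred = NA_real_,
             branched = NA, first_branch_generation = NA_real_,
             error = NA_character_, stringsAsFactors = FALSE)
}

# deterministic per-cell seed below 2^31, derived from base seed, cell and
# replicate indices
cell_seed <- function(base_seed, cell, rep) {
  as.integer((as.double(base_seed) + 1000003 * cell + 7919 * rep) %% 2147483647)
}

#' Run a parameter sweep
#'
#' Evaluates every cell of the grid in \code{spec} and returns one row per
#' cell (per replicate in simulate mode) in a fixed-schema data frame. A
#' failing cell is recorded in its row's \code{error} column and the sweep
#' continues. Simulate-mode cells are seeded deterministically from
#' \code{spec$base_seed} and the cell/replicate index, so the whole sweep is
#' reproducible.
#'
#' @param spec A [sweep_spec()].
#' @param min_persistence Branching persistence threshold (simulate mode).
#' @return Data frame with columns \code{mode, R, lam, s, f, k_h, k_v, k,
#'   seed, x_star, stable, dominant_factor, route_ratio, mean_x, var_x,
#'   realized_R_obs, realized_R_pred, branched, first_branch_generation,
#'   error}.
#' @export
#' @examples
#' sp <- sweep_spec("ess_open", R = c(0.25, 0.5, 1), lambda = 0.5)
#' run_sweep(sp)[, c("R", "x_star")]
run_sweep <- function(spec, min_persistence = 5L) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- spec$grid
  reps <- if (spec$mode == "simulate") spec$replicates else 1L
  rows <- vector("list", nrow(grid) * reps)
  ri <- 1L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (rep in seq_len(reps)) {
      row <- empty_sweep_row(spec$mode)
      row$lam <- g$lam
      row$s <- g$s
      row$f <- g$f
      if (!is.null(g$R)) row$R <- g$R
      if (!is.null(g$k)) {
        row$k <- g$k
        row$k_h <- g$k
        row$k_v <- g$k
      }
      res <- tryCatch({
        switch(spec$mode,
          ess_open = {
            p <- open_params(R = g$R, lambda = g$lam, s = g$s, f = g$f)
            sol <- ess_open(p)
            row$R <- g$R
            row$x_star <- sol$x_star
            row$stable <- sol$stable
            row
          },
          dominance = {
            p <- open_params(R = g$R, lambda = g$lam, s = g$s, f = g$f)
            row$R <- g$R
            row$x_star <- ess_open(p)$x_star
            row$dominant_factor <- dominant_factor_open(p)
            row
          },
          ess_closed = {
            p <- closed_params(lambda = g$lam, k_h = g$k, k_v = g$k,
                               s = g$s, f = g$f)
            sol <- ess_closed(p)
            row$k <- g$k
            row$k_h <- g$k
            row$k_v <- g$k
            row$R <- whole_group_relatedness(p)
            row$x_star <- sol$x_star
            row$stable <- sol$stable
            row
          },
          routes = {
            p <- closed_params(lambda = g$lam, k_h = g$k, k_v = g$k,
                               s = g$s, f = g$f)
            rd <- route_decomposition(p)
            row$k <- g$k
            row$k_h <- g$k
            row$k_v <- g$k
            row$x_star <- ess_closed(p)$x_star
            row$route_ratio <- rd$ratio
            row
          },
          simulate = {
            seed <- cell_seed(spec$base_seed, i, rep)
            args <- utils::modifyList(
              list(n_hosts = 500L, n_generations = 2000L, record_every = 25L),
              spec$sim)
            args$lambda <- g$lam
            args$k <- g$k
            args$s <- g$s
            args$f <- g$f
            args$seed <- seed
            cfg <- do.call(sim_config, args)
            sim <- run_simulation(cfg, keep_snapshots = TRUE)
            bc <- classify_branching(sim, min_persistence = min_persistence)
            cr <- compare_relatedness(sim)
            smry <- sim$summary
            keep <- smry$generation >= 0.25 * cfg$n_generations
            row$k <- g$k
            row$k_h <- g$k
            row$k_v <- g$k
            row$seed <- seed
            row$x_star <- ess_closed(closed_params(
              lambda = g$lam, k_h = g$k, k_v = g$k, s = g$s, f = g$f))$x_star
            row$mean_x <- mean(smry$mean_x[keep])
            row$var_x <- mean(smry$var_x[keep])
            row$realized_R_obs <- cr$observed
            row$realized_R_pred <- cr$predicted
            row$branched <- bc$branched
            row$first_branch_generation <- bc$first_branch_generation
            row
          })
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[ri]] <- res
      ri <- ri + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, sweep_columns]
}

#' Write sweep results to disk
#'
#' Serializes a results table to CSV or JSON with 12 significant digits on
#' the floating-point columns; [read_results()] restores it.
#'
#' @param table Nonempty data frame (typically from [run_sweep()]).
#' @param path Output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("cannot write an empty results table")
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 12L)
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    } else {
      jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                           na = "null", auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed writing results to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read sweep results back from disk
#'
#' @param path File written by [write_results()].
#' @param format \code{"csv"} or \code{"json"}; guessed from the extension
#'   by default.
#' @return The results data frame.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (!file.exists(path)) stop("no such results file: '", path, "'")
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
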