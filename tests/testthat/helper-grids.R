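# shared parameter grids for property-style checks

open_grid <- function(R = c(0.05, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95),
                      lambda = c(0, 0.25, 0.5, 0.75, 1),
                      s = c(0.5, 1, 2), f = c(0.5, 1, 2)) {
  expand.grid(R = R, lambda = lambda, s = s, f = f, KEEP.OUT.ATTRS = FALSE)
}

closed_grid <- function(lambda = seq(0, 1, length.out = 10),
                        k = c(1, 2, 3, 4, 6, 8, 12, 16, 32, 64),
                        s = c(0.5, 1), f = c(0.5, 1, 2, 5, 10)) {
  expand.grid(lambda = lambda, k = k, s = s, f = f, KEEP.OUT.ATTRS = FALSE)
}

# build a fake simulation object from a list of trait matrices, for testing
# trajectory classifiers on constructed fixtures
fake_sim <- function(snapshots, record_every = 25L, x_max = 1 - 1e-6) {
  gens <- (seq_along(snapshots) - 1L) * record_every
  names(snapshots) <- gens
  n_gen <- max(gens)
  cfg <- sim_config(n_hosts = nrow(snapshots[[1]]), k = ncol(snapshots[[1]]),
                    n_generations = max(n_gen, 1L),
                    record_every = record_every, x_max = x_max)
  summary <- data.frame(
    generation = gens,
    mean_x = vapply(snapshots, mean, numeric(1)),
    var_x = vapply(snapshots, function(m) stats::var(as.vector(m)),
                   numeric(1)),
    realized_R = vapply(snapshots, realized_relatedness, numeric(1)),
    n_modes = vapply(snapshots, function(m)
      detect_modes(as.vector(m), x_max = x_max)$n_modes, integer(1)),
    frac_horizontal = NA_real_)
  structure(list(summary = summary, snapshots = snapshots, config = cfg),
            class = "symcoop_sim")
}
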