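test_that("focal symbiont fitness matches term-by-term arithmetic and the resident is neutral", {
  p <- open_params(R = 0.5, lambda = 0.3, s = 1, f = 1)
  expect_equal(symbiont_fitness(0.5, 0.5, 0.5, p), 1)

  # full vertical, defector in a cooperative host: share doubles, host terms 1
  expect_equal(symbiont_fitness(0, 0.5, 0.5, open_params(0.5, 0, 1, 1)), 2)
  # full horizontal drops the fecundity factor entirely
  expect_equal(symbiont_fitness(0.5, 0.5, 0.25, open_params(0.5, 1, 1, 3)), 2)

  # resident fitness is 1 by construction across a parameter grid
  g <- open_grid()
  for (i in seq_len(nrow(g))) {
    p <- open_params(g$R[i], g$lambda[i], g$s[i], g$f[i])
    expect_equal(symbiont_fitness(0.4, 0.4, 0.4, p), 1)
  }

  expect_error(symbiont_fitness(1, 0.5, 0.5, p), "traits")
  expect_error(symbiont_fitness(0.2, 0.2, 0, open_params(0.5, 0, 1, 1)),
               "x_bar")
})

test_that("the selection gradient agrees with its finite-difference assembly from fitness", {
  expect_equal(inclusive_fitness_effect(0.5, open_params(1, 0, 1, 1)), 4)
  expect_equal(inclusive_fitness_effect(0.5, open_params(0, 0.3, 1, 1)), -2)
  expect_error(inclusive_fitness_effect(0, open_params(0.5, 0, 1, 1)))

  h <- 1e-6
  g <- open_grid(R = c(0.2, 0.5, 0.8), lambda = c(0, 0.5, 1))
  for (i in seq_len(nrow(g))) {
    p <- open_params(g$R[i], g$lambda[i], g$s[i], g$f[i])
    for (x in c(0.2, 0.5, 0.8)) {
      dWdxi <- (symbiont_fitness(x + h, x, x, p) -
                  symbiont_fitness(x - h, x, x, p)) / (2 * h)
      dWdxg <- (symbiont_fitness(x, x + h, x, p) -
                  symbiont_fitness(x, x - h, x, p)) / (2 * h)
      val <- inclusive_fitness_effect(x, p)
      expect_lt(abs(val - (dWdxi + p$R * dWdxg)), 1e-6 * max(1, abs(val)))
    }
  }
})

test_that("the open-model ESS solves the gradient, respects boundaries and is stable", {
  expect_identical(ess_open(open_params(1, 0.5, 1, 1))$x_star, 1)
  expect_identical(ess_open(open_params(0, 0.2, 1, 2))$x_star, 0)
  expect_equal(ess_open(open_params(0.25, 0.5, 1, 2))$x_star, 0.4)
  # s = f = 0 means no host benefit: boundary zero
  expect_identical(ess_open(open_params(0.7, 0.3, 0, 0))$x_star, 0)

  g <- open_grid()
  for (i in seq_len(nrow(g))) {
    sol <- ess_open(open_params(g$R[i], g$lambda[i], g$s[i], g$f[i]))
    expect_gte(sol$x_star, 0)
    expect_lte(sol$x_star, 1)
    expect_true(sol$stable)
    if (sol$x_star > 0 && sol$x_star < 1)
      expect_lt(abs(sol$delta_if_residual), 1e-10)
  }
})

test_that("the open-model ESS is monotone in each parameter", {
  base <- list(R = 0.5, lambda = 0.5, s = 1, f = 1)
  along <- function(name, values) {
    vapply(values, function(v) {
      a <- base; a[[name]] <- v
      ess_open(open_params(a$R, a$lambda, a$s, a$f))$x_star
    }, numeric(1))
  }
  grid <- seq(0, 1, by = 0.05)
  expect_true(all(diff(along("R", grid)) >= 0))
  expect_true(all(diff(along("lambda", grid)) <= 0))
  expect_true(all(diff(along("s", seq(0, 5, by = 0.25))) >= 0))
  expect_true(all(diff(along("f", seq(0, 5, by = 0.25))) >= 0))
})

test_that("demographic whole-group relatedness matches the closed form and its limits", {
  expect_identical(whole_group_relatedness(closed_params(0, 10, 10)), 1)
  expect_equal(whole_group_relatedness(closed_params(1, 4, 7)), 0.25)
  expect_equal(whole_group_relatedness(closed_params(0.5, 2, 10)), 6 / 11)

  # equal bottlenecks reduce to 1/(1 + lambda (k-1)); nonincreasing in both
  for (k in c(1, 2, 5, 20)) {
    r <- vapply(seq(0, 1, by = 0.1), function(lam)
      whole_group_relatedness(closed_params(lam, k, k)), numeric(1))
    expect_equal(r, 1 / (1 + seq(0, 1, by = 0.1) * (k - 1)))
    expect_true(all(diff(r) <= 0))
    expect_true(all(r > 0 & r <= 1))
  }
  r_k <- vapply(c(1, 2, 4, 8, 16), function(k)
    whole_group_relatedness(closed_params(0.6, k, k)), numeric(1))
  expect_true(all(diff(r_k) <= 0))
})

test_that("the closed-model ESS equals the open ESS at the demographic relatedness", {
  expect_equal(ess_closed(closed_params(1, 4, 4, 1, 1))$x_star, 0.25)
  expect_identical(ess_closed(closed_params(0, 20, 20, 1, 1))$x_star, 1)
  expect_equal(ess_closed(closed_params(0.5, 10, 10, 1, 2))$x_star, 2 / 6.5)
  expect_error(ess_closed(closed_params(0.5, 2, 3)), "equal bottlenecks")

  g <- closed_grid(lambda = c(0, 0.3, 0.7, 1), k = c(1, 2, 8, 32),
                   s = c(0.5, 1), f = c(1, 5))
  for (i in seq_len(nrow(g))) {
    p <- closed_params(g$lambda[i], g$k[i], g$k[i], g$s[i], g$f[i])
    po <- open_params(whole_group_relatedness(p), p$lambda, p$s, p$f)
    expect_equal(ess_closed(p)$x_star, ess_open(po)$x_star, tolerance = 1e-12)
  }

  # nonincreasing in lambda and in k
  xs <- vapply(seq(0, 1, by = 0.1), function(lam)
    ess_closed(closed_params(lam, 4, 4, 1, 1))$x_star, numeric(1))
  expect_true(all(diff(xs) <= 0))
  xs_k <- vapply(c(1, 2, 4, 8, 16), function(k)
    ess_closed(closed_params(0.5, k, k, 1, 1))$x_star, numeric(1))
  expect_true(all(diff(xs_k) <= 0))
})

test_that("closed-form marginal effects match finite differences of the ESS", {
  expect_equal(marginal_effect_relatedness(open_params(0.5, 0, 1, 1)),
               2 / 2.25)
  expect_equal(marginal_effect_transmission(open_params(0.5, 0, 1, 1)),
               -0.25 / 2.25)
  expect_equal(marginal_effect_relatedness(open_params(0.5, 1, 0, 3)), 0)
  expect_equal(marginal_effect_transmission(open_params(1, 0.4, 1, 2)), 0)
  expect_equal(marginal_effect_transmission(open_params(0, 0.4, 1, 2)), 0)

  h <- 1e-6
  g <- open_grid(R = c(0.2, 0.5, 0.8), lambda = c(0.25, 0.5, 0.75))
  for (i in seq_len(nrow(g))) {
    a <- g[i, ]
    fd_R <- (ess_open(open_params(a$R + h, a$lambda, a$s, a$f))$x_star -
               ess_open(open_params(a$R - h, a$lambda, a$s, a$f))$x_star) / (2 * h)
    fd_l <- (ess_open(open_params(a$R, a$lambda + h, a$s, a$f))$x_star -
               ess_open(open_params(a$R, a$lambda - h, a$s, a$f))$x_star) / (2 * h)
    p <- open_params(a$R, a$lambda, a$s, a$f)
    expect_equal(marginal_effect_relatedness(p), fd_R, tolerance = 1e-4)
    expect_equal(marginal_effect_transmission(p), fd_l, tolerance = 1e-4)
    expect_gte(marginal_effect_relatedness(p), 0)
    expect_lte(marginal_effect_transmission(p), 0)
  }
})

test_that("dominance labels follow the marginal-effect comparison, with ties reported", {
  expect_identical(dominant_factor_open(open_params(0.5, 0.9, 0.1, 10)),
                   "transmission")
  expect_identical(dominant_factor_open(open_params(0.5, 0.5, 1, 1)),
                   "relatedness")
  expect_identical(dominant_factor_open(open_params(1, 0.3, 1, 5)),
                   "relatedness")
  # exact boundary f R(1-R) = f(1-lambda) + s: R=0.5, f=8, s=1, lambda=7/8
  expect_identical(dominant_factor_open(open_params(0.5, 7 / 8, 1, 8)), "tie")
})

test_that("route decomposition is additive and its ratio follows A/(f lambda)", {
  rd <- route_decomposition(closed_params(0.5, 4, 4, 1, 1))
  expect_equal(rd$ratio, 3)
  expect_equal(rd$total, rd$direct + rd$indirect)
  expect_equal(route_decomposition(closed_params(1, 4, 4, 1, 2))$ratio, 0.5)
  expect_identical(route_decomposition(closed_params(0, 4, 4, 1, 1))$ratio, Inf)
  expect_identical(route_decomposition(closed_params(0.5, 4, 4, 1, 0))$ratio, Inf)
  expect_error(route_decomposition(closed_params(0.5, 1, 1)), "k >= 2")

  # total derivative agrees with a finite difference of the closed-model ESS
  h <- 1e-6
  for (lam in c(0.25, 0.5, 0.9)) {
    for (k in c(2, 4, 8)) {
      rd <- route_decomposition(closed_params(lam, k, k, 1, 2))
      fd <- (ess_closed(closed_params(lam + h, k, k, 1, 2))$x_star -
               ess_closed(closed_params(lam - h, k, k, 1, 2))$x_star) / (2 * h)
      expect_equal(rd$total, fd, tolerance = 1e-4)
      # direct route agrees with the open-model derivative at the pinned R
      p_open <- open_params(whole_group_relatedness(closed_params(lam, k, k)),
                            lam, 1, 2)
      expect_equal(rd$direct, marginal_effect_transmission(p_open),
                   tolerance = 1e-12)
    }
  }
})

test_that("the finite-difference oracle reproduces the closed-form ESS", {
  expect_equal(numeric_ess_oracle(open_params(0.5, 0, 1, 1)), 2 / 3,
               tolerance = 1e-6)
  expect_identical(numeric_ess_oracle(open_params(0, 0.5, 1, 1)), 0)
  expect_gt(numeric_ess_oracle(open_params(1, 0.5, 1, 1)), 0.9999)

  g <- open_grid(R = c(0.1, 0.3, 0.6, 0.9), lambda = c(0, 0.5, 1),
                 s = c(0.5, 2), f = c(0.5, 2))
  for (i in seq_len(nrow(g))) {
    p <- open_params(g$R[i], g$lambda[i], g$s[i], g$f[i])
    expect_equal(numeric_ess_oracle(p), ess_open(p)$x_star, tolerance = 1e-6)
  }
})

test_that("parameter constructors reject out-of-domain values", {
  expect_error(open_params(-0.1, 0.5, 1, 1), "R")
  expect_error(open_params(0.5, 1.5, 1, 1), "lambda")
  expect_error(open_params(0.5, 0.5, -1, 1), "s")
  expect_error(closed_params(0.5, 2.5, 3), "k_h")
  expect_error(closed_params(0.5, 0, 3), "k_h")
  expect_error(closed_params(2, 2, 2), "lambda")
})
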