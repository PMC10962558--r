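test_that("step constant matches its closed form", {
  z <- qnorm(0.95)
  expect_equal(step_constant(0.05), 2 * z * exp(-z^2 / 2) / sqrt(2 * pi))
  expect_lt(abs(step_constant(0.05) - 0.3392), 1e-3)
  expect_equal(step_constant(0.5), 0)
  # k = 2 z dnorm(z) peaks where z = 1, i.e. alpha* = 1 - pnorm(1)
  apeak <- 1 - pnorm(1)
  left <- seq(0.01, apeak - 0.01, by = 0.01)
  right <- seq(apeak + 0.01, 0.49, by = 0.01)
  expect_true(all(diff(step_constant(left)) > 0))
  expect_true(all(diff(step_constant(right)) < 0))
  expect_error(step_constant(0), class = "permcrt_argument_error")
  expect_error(step_constant(1), class = "permcrt_argument_error")
})

test_that("bound updates move by the prescribed step", {
  expect_equal(update_bound(1, s = 0.3, alpha_star = 0.05, q = 4,
                            rejected = TRUE, side = "upper"), 0.99625)
  expect_equal(update_bound(1, s = 0.3, alpha_star = 0.05, q = 4,
                            rejected = FALSE, side = "upper"), 1.07125)
  expect_equal(update_bound(1, s = 0.3, alpha_star = 0.05, q = 4,
                            rejected = TRUE, side = "lower"), 1.00375)
  expect_equal(update_bound(1, s = 0.3, alpha_star = 0.05, q = 4,
                            rejected = FALSE, side = "lower"), 0.92875)
})

test_that("the recursion converges to a known quantile on a Bernoulli oracle", {
  # synthetic rejection oracle: reject with probability F(b); the upper
  # recursion settles where F(b) = 1 - alpha*
  # 1/q steps give a finite travel budget (~ s log Q), so the recursion is
  # an equilibrium-locator: started near the quantile it stays pinned to it,
  # from either side
  set.seed(43)
  alpha_star <- 0.05
  Fb <- function(b) pnorm((b - 2) / 0.5)
  target <- 2 + 0.5 * qnorm(1 - alpha_star)
  k <- step_constant(alpha_star)
  run_from <- function(b0) {
    b <- b0
    for (q in 1:6000) {
      s <- max(k * (b - 2), 0.01)
      b <- update_bound(b, s, alpha_star, q, runif(1) < Fb(b), "upper")
    }
    b
  }
  from_above <- replicate(5, run_from(2.95))
  from_below <- replicate(5, run_from(2.70))
  expect_lt(abs(mean(from_above) - target), 0.1)
  expect_lt(abs(mean(from_below) - target), 0.1)
})

test_that("search traces have the documented shape and starting values", {
  trial <- simulate_crt(crt_scenario(1, clusters_per_arm = 4), seed = 19)
  fits <- suppressMessages(lapply(outcome_specs(trial), fit_nuisance,
                                  data = trial))
  Q <- 150
  ci <- crt_ci(trial, method = "romano_wolf", Q = Q, seed = 4, fits = fits)
  expect_equal(nrow(ci$trace), Q * 2 * 2)  # Q steps x 2 sides x 2 outcomes
  start <- ci$trace[ci$trace$iteration == 1, ]
  dh <- vapply(fits, `[[`, 0, "delta_hat")
  se <- vapply(fits, `[[`, 0, "se_hat")
  expect_equal(start$value[start$side == "upper"], unname(dh + 2 * se))
  expect_equal(start$value[start$side == "lower"], unname(dh - 2 * se))
  expect_true(all(ci$results$lower <= ci$results$upper))
  expect_warning(crt_ci(trial, Q = 50, seed = 1, fits = fits), "unreliable")
})

test_that("convergence diagnostics separate flat from drifting tails", {
  flat <- tidyr::expand_grid(side = "upper", outcome = "y1",
                             iteration = 1:400)
  flat$value <- c(seq(2, 1, length.out = 100), rep(1, 300)) +
    rnorm(400, sd = 1e-4)
  diag_flat <- convergence_diagnostic(flat, width = c(y1 = 1))
  expect_true(all(diag_flat$converged))

  ramp <- flat
  ramp$value <- seq(2, 1, length.out = 400)
  diag_ramp <- convergence_diagnostic(ramp, width = c(y1 = 1))
  expect_false(any(diag_ramp$converged))
})

test_that("single-outcome search limits match the grid-inversion oracle", {
  # a design large enough that the exact permutation limits sit near the
  # delta_hat +/- 2 SE starting values, where the 1/q search operates well
  sc <- crt_scenario(1, clusters_per_arm = 7, n_per_cluster = 10,
                     delta = c(0.3, 0))
  trial <- simulate_crt(sc, seed = 23)
  fit <- suppressMessages(fit_nuisance(trial, outcome_specs(trial)$y1))
  oracle <- grid_ci_oracle(trial, fit, by = 0.05)

  ci1 <- crt_ci(trial, outcomes = list(outcome_specs(trial)$y1),
                method = "none", Q = 10000, seed = 31, fits = list(fit))
  ci2 <- crt_ci(trial, outcomes = list(outcome_specs(trial)$y1),
                method = "none", Q = 10000, seed = 77, fits = list(fit))
  tol <- 0.25 * fit$se_hat
  expect_lt(abs(ci1$results$lower - oracle[1]), tol)
  expect_lt(abs(ci1$results$upper - oracle[2]), tol)
  # seed stability on a convergent problem: within the diagnostic tolerance
  # (a fraction of the interval width)
  wtol <- 0.15 * (ci1$results$upper - ci1$results$lower)
  expect_lt(abs(ci1$results$lower - ci2$results$lower), wtol)
  expect_lt(abs(ci1$results$upper - ci2$results$upper), wtol)
})

test_that("autoplot of a search returns a trace plot", {
  trial <- simulate_crt(crt_scenario(1, clusters_per_arm = 3), seed = 2)
  fits <- suppressMessages(lapply(outcome_specs(trial), fit_nuisance,
                                  data = trial))
  ci <- suppressWarnings(crt_ci(trial, Q = 60, seed = 1, fits = fits))
  p <- autoplot(ci)
  expect_s3_class(p, "ggplot")
})
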