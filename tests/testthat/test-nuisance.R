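test_that("degenerate cluster variance recovers the OLS difference in means", {
  trial <- simulate_crt(crt_scenario(1, tau = 0), seed = 5)
  fit <- suppressMessages(fit_nuisance(trial, outcome_specs(trial)$y1))
  ols <- stats::lm(y1 ~ treatment, data = trial)
  expect_lt(fit$theta_hat$tau2, 1e-3)
  expect_equal(fit$delta_hat, unname(coef(ols)["treatment"]), tolerance = 1e-4)
})

test_that("nuisance estimates are unbiased for the Gaussian model at 14 clusters", {
  n_reps <- 150
  sc <- crt_scenario(1)
  est <- matrix(NA_real_, n_reps, 3)
  for (i in seq_len(n_reps)) {
    trial <- simulate_crt(sc, seed = 3000 + i)
    fit <- suppressMessages(fit_nuisance(trial, outcome_specs(trial)$y1))
    est[i, ] <- c(fit$delta_hat, fit$theta_hat$sigma2, fit$theta_hat$tau2)
  }
  mc_se <- apply(est, 2, sd) / sqrt(n_reps)
  expect_lt(abs(mean(est[, 1]) - 0), 3 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - 1), 3 * mc_se[2])
  # ML variance-component estimates carry small downward bias at C = 28;
  # allow it on top of Monte-Carlo error
  expect_lt(abs(mean(est[, 3]) - 0.05), 3 * mc_se[3] + 0.01)
  icc <- est[, 3] / (est[, 3] + est[, 2])
  expect_equal(mean(icc), 0.05, tolerance = 0.3)
})

test_that("degenerate outcomes produce errors, not silent failures", {
  df <- tibble::tibble(cluster = rep(1:4, each = 3),
                       treatment = rep(c(1, 1, 0, 0), each = 3),
                       y = 0L)
  trial <- crt_data(df, outcomes = list(outcome_spec("y", "poisson")))
  expect_error(fit_nuisance(trial, outcome_specs(trial)$y),
               class = "permcrt_fit_error")
})

test_that("plug-in null means follow the stated link formulas", {
  df <- tibble::tibble(cluster = rep(1:2, each = 2),
                       treatment = rep(c(1, 0), each = 2),
                       y = rpois(4, 3))
  trial <- crt_data(df, outcomes = list(outcome_spec("y", "poisson")))
  fit <- make_fit(trial, family = "poisson", mu0 = 1)

  mu0 <- null_marginal_means(fit, trial, delta_star = 0, refit = FALSE)
  expect_equal(mu0, rep(exp(1), 4))
  mu <- null_marginal_means(fit, trial, delta_star = 0.5, refit = FALSE)
  expect_equal(mu[trial$treatment == 1], rep(exp(1.5), 2))
  expect_equal(mu[trial$treatment == 0], mu0[trial$treatment == 0])

  gfit <- make_fit(trial, family = "gaussian", mu0 = 1)
  expect_equal(null_marginal_means(gfit, trial, 0, refit = FALSE), rep(1, 4))
  expect_error(null_marginal_means(gfit, trial, Inf),
               class = "permcrt_argument_error")
})

test_that("null refit agrees with glm fit with a treatment offset", {
  trial <- simulate_crt(crt_scenario(2), seed = 8)
  for (nm in c("y1", "y2")) {
    fit <- suppressMessages(fit_nuisance(trial, outcome_specs(trial)[[nm]]))
    for (d in c(0, 0.3)) {
      fam <- switch(fit$spec$family, poisson = poisson(), gaussian = gaussian())
      ref <- stats::glm(trial[[nm]] ~ 1, family = fam,
                        offset = d * trial$treatment)
      ours <- null_fixed_effects <- permcrt:::null_fixed_effects(fit, d)
      expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-6)
    }
  }
  # multi-period design with a period fixed effect (bernoulli included)
  tr3 <- simulate_crt(crt_scenario(3), seed = 9)
  fit3 <- fit_nuisance(tr3, outcome_specs(tr3)$y3, engine = "glm",
                       theta = list(tau2 = 1, lambda = 0.7))
  ref3 <- stats::glm(tr3$y3 ~ factor(tr3$time), family = binomial(),
                     offset = 0.4 * tr3$treatment)
  ours3 <- permcrt:::null_fixed_effects(fit3, 0.4)
  expect_equal(sort(unname(ours3$beta)), sort(unname(coef(ref3))),
               tolerance = 1e-6)
})

test_that("cluster covariance matrices have the exchangeable structure", {
  df <- tibble::tibble(cluster = rep(1:2, each = 3),
                       treatment = rep(c(1, 0), each = 3),
                       y = rnorm(6))
  trial <- crt_data(df, outcomes = "y")
  fit <- make_fit(trial, sigma2 = 1, tau2 = 0.05)
  cov <- build_cluster_covariance(fit, trial)
  V <- cov[[1]]$V
  expect_equal(diag(V), rep(1.05, 3))
  expect_equal(V[lower.tri(V)], rep(0.05, 3))
  expect_lt(max(abs(cov[[1]]$V %*% cov[[1]]$Vinv - diag(3))), 1e-8)

  fit0 <- make_fit(trial, sigma2 = 2, tau2 = 0)
  cov0 <- build_cluster_covariance(fit0, trial)
  expect_equal(cov0[[1]]$V, diag(2, 3))
})

test_that("AR-decay covariance decays across periods and needs lambda", {
  tr3 <- simulate_crt(crt_scenario(3, clusters_per_arm = 2,
                                   n_per_cluster = 2), seed = 2)
  fit <- fit_nuisance(tr3, outcome_specs(tr3)$y2, engine = "glm",
                      theta = list(tau2 = 0.5, lambda = 0.6))
  cov <- build_cluster_covariance(fit, tr3)
  V <- cov[[1]]$V
  tt <- tr3$time[cov[[1]]$rows]
  off <- V[1, which(tt != tt[1])[1]]
  expect_equal(off, 0.5 * 0.6)          # cross-period: tau2 * lambda
  expect_equal(V[1, which(tt == tt[1])[2]], 0.5)  # same period: tau2

  fit_nl <- fit_nuisance(tr3, outcome_specs(tr3)$y2, engine = "glm",
                         theta = list(tau2 = 0.5))
  expect_error(build_cluster_covariance(fit_nl, tr3),
               class = "permcrt_config_error")
})

test_that("random SPD covariances invert to numerical identity", {
  set.seed(41)
  df <- tibble::tibble(cluster = rep(1:3, each = 5),
                       treatment = rep(c(1, 0, 0), each = 5),
                       y = rnorm(15))
  trial <- crt_data(df, outcomes = "y")
  for (i in 1:5) {
    fit <- make_fit(trial, sigma2 = runif(1, 0.2, 3), tau2 = runif(1, 0, 1))
    cov <- build_cluster_covariance(fit, trial)
    worst <- max(vapply(cov, function(b)
      max(abs(b$V %*% b$Vinv - diag(nrow(b$V)))), numeric(1)))
    expect_lt(worst, 1e-8)
  }
})

test_that("nuisance quantities are bit-identical across permutation runs", {
  trial <- simulate_crt(crt_scenario(2, clusters_per_arm = 4), seed = 6)
  fits <- suppressMessages(lapply(outcome_specs(trial), fit_nuisance,
                                  data = trial))
  covs <- lapply(fits, build_cluster_covariance, data = trial)
  snap <- serialize(list(fits, covs), NULL)
  invisible(permutation_matrix(trial, fits, plan = permutation_plan(M = 50, seed = 1),
                               mode = "weighted", covs = covs))
  expect_identical(serialize(list(fits, covs), NULL), snap)
})
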