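#' Define a simulation scenario for a multi-outcome cluster trial
#'
#' Three data-generating processes of rising complexity, mirroring common
#' cluster-trial designs:
#'
#' * **Model 1** — two-arm parallel trial, two Gaussian outcomes with
#'   between-outcome correlation `rho` at the individual level and `pi` at
#'   the cluster level.
#' * **Model 2** — two-arm parallel trial; outcome 1 Poisson (log link),
#'   outcome 2 Gaussian, independent cluster random effects (`pi = 0`).
#' * **Model 3** — two periods with baseline measures: treated clusters
#'   switch on in period 2; three outcomes (Poisson, Gaussian,
#'   Bernoulli-logit) with cluster-period random effects correlated across
#'   periods as `tau^2 lambda^|t - t'|` and independent across outcomes.
#'
#' Defaults reproduce the reference study conditions: `mu = 1`,
#' `sigma^2 = 1`, `tau^2 = 0.05` (marginal ICC 0.05) for models 1-2 with 7
#' clusters per arm and 20 individuals per cluster; `mu = -1`, `tau = 1`,
#' `lambda = 0.7` for model 3.
#'
#' @param model 1, 2, or 3.
#' @param clusters_per_arm Clusters per arm (1:1 allocation).
#' @param n_per_cluster Individuals per cluster (per period).
#' @param delta True treatment effects, one per outcome.
#' @param mu Intercepts, one per outcome.
#' @param sigma Individual-level Gaussian SDs.
#' @param tau Cluster(-period) random-effect SDs.
#' @param rho,pi Individual- and cluster-level between-outcome correlations
#'   (model 1; model 2 uses `pi = 0`).
#' @param lambda Temporal decay of the cluster-period random effects
#'   (model 3).
#' @param period_effect Fixed effect of the second period (model 3).
#' @return A list of class `crt_scenario`.
#' @examples
#' crt_scenario(2, delta = c(0, 0.5))
#' @export
crt_scenario <- function(model = c(1, 2, 3),
                         clusters_per_arm = 7,
                         n_per_cluster = 20,
                         delta = NULL, mu = NULL, sigma = NULL, tau = NULL,
                         rho = 0, pi = 0, lambda = 0.7,
                         period_effect = 0.5) {
  model <- as.integer(model[1])
  stopifnot(model %in% 1:3)
  J <- if (model == 3) 3L else 2L
  delta <- rep_len(delta %||% 0, J)
  mu <- rep_len(mu %||% (if (model == 3) -1 else 1), J)
  sigma <- rep_len(sigma %||% 1, J)
  tau <- rep_len(tau %||% (if (model == 3) 1 else sqrt(0.05)), J)
  if (abs(rho) > 1 || abs(pi) > 1)
    abort("correlations must lie in [-1, 1]", class = "permcrt_config_error")
  if (any(sigma < 0) || any(tau < 0))
    abort("standard deviations must be nonnegative", class = "permcrt_config_error")
  families <- switch(model,
                     `1` = c("gaussian", "gaussian"),
                     `2` = c("poisson", "gaussian"),
                     `3` = c("poisson", "gaussian", "bernoulli"))
  structure(list(model = model, clusters_per_arm = clusters_per_arm,
                 n_per_cluster = n_per_cluster, J = J, delta = delta,
                 mu = mu, sigma = sigma, tau = tau, rho = rho, pi = pi,
                 lambda = lambda, period_effect = period_effect,
                 families = families),
            class = "crt_scenario")
}

#' @export
print.crt_scenario <- function(x, ...) {
  cat(sprintf("<crt_scenario> model %d: %s; %d clusters/arm x %d; delta = (%s)\n",
              x$model, paste(x$families, collapse = "+"),
              x$clusters_per_arm, x$n_per_cluster,
              paste(x$delta, collapse = ", ")))
  invisible(x)
}

# Draw n samples from N(0, Sigma); Sigma may be positive semi-definite
# (zero variance components are legitimate boundary cases).
rmvn <- function(n, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) {
    eg <- eigen(Sigma, symmetric = TRUE)
    if (any(eg$values < -1e-8 * max(abs(eg$values), 1)))
      abort("implied random-effect covariance is not positive semi-definite",
            class = "permcrt_numeric_error")
    t(eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0))))
  })
  matrix(rnorm(n * ncol(Sigma)), n) %*% R
}

#' Simulate a trial dataset from a scenario
#'
#' Generates one replicate dataset from the scenario's data-generating
#' process. The treated arm is drawn uniformly over 1:1 splits of the
#' clusters, so the identity of the treated clusters is itself randomized
#' per replicate. The same `(scenario, seed)` pair reproduces the dataset
#' bit-identically.
#'
#' @param scenario A [crt_scenario()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `crt_data` tibble with outcome columns `y1`, `y2` (and `y3`
#'   for model 3).
#' @examples
#' trial <- simulate_crt(crt_scenario(1, delta = c(0, 0.5)), seed = 42)
#' cluster_periods(trial)
#' @export
simulate_crt <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "crt_scenario"))
  if (!is.null(seed)) set.seed(seed)
  s <- scenario
  C <- 2L * s$clusters_per_arm
  n <- s$n_per_cluster
  treated <- sort(sample.int(C, s$clusters_per_arm))
  Dc <- as.integer(seq_len(C) %in% treated)

  if (s$model %in% c(1L, 2L)) {
    cl <- rep(seq_len(C), each = n)
    D <- Dc[cl]
    if (s$model == 1L) {
      Sig_th <- matrix(c(s$tau[1]^2, s$pi * s$tau[1] * s$tau[2],
                         s$pi * s$tau[1] * s$tau[2], s$tau[2]^2), 2)
      Sig_e <- matrix(c(s$sigma[1]^2, s$rho * s$sigma[1] * s$sigma[2],
                        s$rho * s$sigma[1] * s$sigma[2], s$sigma[2]^2), 2)
      th <- rmvn(C, Sig_th)
      e <- rmvn(C * n, Sig_e)
      y1 <- s$mu[1] + s$delta[1] * D + th[cl, 1] + e[, 1]
      y2 <- s$mu[2] + s$delta[2] * D + th[cl, 2] + e[, 2]
    } else {
      th1 <- rnorm(C, 0, s$tau[1])
      th2 <- rnorm(C, 0, s$tau[2])
      y1 <- rpois(C * n, exp(s$mu[1] + s$delta[1] * D + th1[cl]))
      y2 <- rnorm(C * n, s$mu[2] + s$delta[2] * D + th2[cl], s$sigma[2])
    }
    df <- tibble::tibble(cluster = cl, time = 1L, treatment = D,
                         y1 = y1, y2 = y2)
  } else {
    Tt <- 2L
    cl <- rep(seq_len(C), each = n * Tt)
    tm <- rep(rep(seq_len(Tt), each = n), times = C)
    D <- as.integer(Dc[cl] == 1L & tm == 2L)  # rollout in period 2
    Sig_t <- s$lambda^abs(outer(1:Tt, 1:Tt, "-"))
    th <- lapply(seq_len(s$J), function(j) rmvn(C, s$tau[j]^2 * Sig_t))
    idx <- cbind(cl, tm)
    per <- s$period_effect * (tm == 2L)
    eta <- lapply(seq_len(s$J), function(j)
      s$mu[j] + s$delta[j] * D + per + th[[j]][idx])
    y1 <- rpois(length(cl), exp(eta[[1]]))
    y2 <- rnorm(length(cl), eta[[2]], s$sigma[2])
    y3 <- rbinom(length(cl), 1, plogis(eta[[3]]))
    df <- tibble::tibble(cluster = cl, time = tm, treatment = D,
                         y1 = y1, y2 = y2, y3 = y3)
  }

  specs <- lapply(seq_len(s$J), function(j)
    outcome_spec(paste0("y", j), s$families[j]))
  crt_data(df, outcomes = specs, cluster = "cluster",
           treatment = "treatment", time = "time")
}
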