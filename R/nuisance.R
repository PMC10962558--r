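fam_linkinv <- function(family) {
  switch(family,
         gaussian = identity,
         poisson = exp,
         bernoulli = plogis)
}

fam_variance <- function(family) {
  switch(family,
         gaussian = function(mu, sigma2) rep_len(sigma2, length(mu)),
         poisson = function(mu, sigma2) mu,
         bernoulli = function(mu, sigma2) mu * (1 - mu))
}

# (d h^-1 / d eta)^-1 at mu: ones for identity, 1/mu for log,
# (mu(1-mu))^-1 for logit
fam_gweight <- function(family) {
  switch(family,
         gaussian = function(mu) rep_len(1, length(mu)),
         poisson = function(mu) 1 / mu,
         bernoulli = function(mu) 1 / (mu * (1 - mu)))
}

#' Fit the univariate nuisance model for one outcome
#'
#' Fits the generalized linear mixed model with linear predictor
#' `mu0 + delta * D + X beta (+ period effects) + theta_c` for a single
#' outcome, returning the treatment-effect estimate, its model-based standard
#' error, and the variance components needed to build cluster covariance
#' matrices. These nuisance quantities are estimated once and then frozen for
#' all permutations: permutation validity requires that parameters other than
#' the treatment effect be invariant to the permutation.
#'
#' Gaussian outcomes use `lme4::lmer` (maximum likelihood by default),
#' Poisson and Bernoulli outcomes `lme4::glmer` with the Laplace
#' approximation. `engine = "glm"` forces a fixed-effects-only fit (used for
#' multi-period designs with autoregressive random effects, where mixed
#' software support is limited); variance components may then be supplied
#' through `theta`. A mixed fit that fails to converge falls back to the
#' fixed-effects fit with a warning.
#'
#' @param data A `crt_data` object.
#' @param spec An [outcome_spec()]; defaults to the first outcome of `data`.
#' @param engine `"auto"` (mixed model, glm fallback), `"mixed"`, or `"glm"`.
#' @param reml Use REML instead of ML for Gaussian mixed fits.
#' @param covariance Random-effect covariance structure used when building
#'   cluster covariance matrices: `"exchangeable"` (default for single-period
#'   designs), `"ar_decay"` (multi-period, correlation decaying as
#'   `lambda^|t-t'|`), or `"independence"`.
#' @param theta Optional named list overriding variance components:
#'   `sigma2`, `tau2`, `lambda`.
#'
#' @return An object of class `crt_fit`: a list with elements `spec`,
#'   `delta_hat`, `se_hat`, `coefficients`, `theta_hat` (list `sigma2`,
#'   `tau2`, `lambda`), `eta_base` (fixed-effect linear predictor with the
#'   treatment term removed), `treatment`, `engine`, `converged`.
#' @examples
#' trial <- simulate_crt(crt_scenario(2), seed = 1)
#' fit <- fit_nuisance(trial, outcome_specs(trial)$y1)
#' tidy(fit)
#' @export
fit_nuisance <- function(data, spec = NULL,
                         engine = c("auto", "mixed", "glm"),
                         reml = FALSE,
                         covariance = NULL,
                         theta = NULL) {
  engine <- match.arg(engine)
  spec <- spec %||% outcome_specs(data)[[1L]]
  stopifnot(inherits(spec, "outcome_spec"))
  multiperiod <- length(unique(data$time)) > 1L
  covariance <- covariance %||% if (multiperiod) "ar_decay" else "exchangeable"
  covariance <- match.arg(covariance, c("exchangeable", "ar_decay", "independence"))
  if (covariance == "ar_decay" && !multiperiod)
    abort("ar_decay covariance requires more than one period",
          class = "permcrt_config_error")

  y <- data[[spec$name]]
  if (spec$family == "poisson" && all(y == 0))
    abort(sprintf("outcome '%s' is all zeros; poisson fit is degenerate", spec$name),
          class = "permcrt_fit_error")

  df <- as.data.frame(data)
  df$.y <- y
  rhs <- c("treatment", spec$covariates, if (multiperiod) "factor(time)")
  fam <- switch(spec$family, gaussian = gaussian(), poisson = poisson(),
                bernoulli = binomial())

  fit_glm <- function() {
    f <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
    m <- if (spec$family == "gaussian") stats::lm(f, data = df)
         else stats::glm(f, data = df, family = fam)
    if (any(!is.finite(coef(m))))
      abort(sprintf("singular design for outcome '%s': %s", spec$name,
                    paste(names(coef(m))[!is.finite(coef(m))], collapse = ", ")),
            class = "permcrt_fit_error")
    sm <- summary(m)$coefficients
    list(model = m, coefs = coef(m), table = sm,
         sigma2 = if (spec$family == "gaussian") summary(m)$sigma^2 else NA_real_,
         tau2 = 0, mixed = FALSE, converged = TRUE)
  }

  fit_mixed <- function() {
    f <- as.formula(paste(".y ~", paste(rhs, collapse = " + "), "+ (1 | cluster)"))
    m <- if (spec$family == "gaussian") {
      lme4::lmer(f, data = df, REML = reml)
    } else {
      lme4::glmer(f, data = df, family = fam)
    }
    # marginal gradient warnings from lme4 are recorded, not treated as
    # failures; hard errors still trigger the fixed-effects fallback
    msgs <- m@optinfo$conv$lme4$messages
    conv <- is.null(msgs) ||
      !any(grepl("failed to converge", msgs, ignore.case = TRUE))
    sm <- coef(summary(m))
    vc <- as.data.frame(lme4::VarCorr(m))
    tau2 <- vc$vcov[vc$grp == "cluster"][1]
    list(model = m, coefs = lme4::fixef(m), table = sm,
         sigma2 = if (spec$family == "gaussian") stats::sigma(m)^2 else NA_real_,
         tau2 = tau2, mixed = TRUE, converged = conv)
  }

  res <- if (engine == "glm") {
    fit_glm()
  } else if (engine == "mixed") {
    fit_mixed()
  } else {
    tryCatch(fit_mixed(), error = function(e) {
      warn(sprintf("mixed fit failed for outcome '%s' (%s); falling back to fixed-effects fit",
                   spec$name, conditionMessage(e)))
      fit_glm()
    })
  }

  if (!is.null(theta)) {
    if (!is.null(theta$sigma2)) res$sigma2 <- theta$sigma2
    if (!is.null(theta$tau2)) res$tau2 <- theta$tau2
  }
  lambda <- theta$lambda %||% NA_real_

  tab <- res$table
  delta_hat <- unname(res$coefs["treatment"])
  se_hat <- unname(tab["treatment", "Std. Error"])
  if (!is.finite(delta_hat) || !is.finite(se_hat) || se_hat <= 0)
    abort(sprintf("treatment effect estimate for '%s' is degenerate", spec$name),
          class = "permcrt_fit_error")

  # fixed-effect linear predictor with the treatment contribution removed
  # (plug-in path), plus the non-treatment design matrix for null re-fits
  X <- stats::model.matrix(res$model)
  eta_fixed <- drop(X %*% res$coefs[colnames(X)])
  eta_base <- eta_fixed - delta_hat * data$treatment
  keep <- setdiff(colnames(X), "treatment")
  Xf <- X[, keep, drop = FALSE]

  structure(
    list(spec = spec,
         delta_hat = delta_hat,
         se_hat = se_hat,
         coefficients = res$coefs,
         theta_hat = list(sigma2 = res$sigma2, tau2 = res$tau2, lambda = lambda),
         covariance = covariance,
         eta_base = eta_base,
         Xf = Xf,
         Xf_beta = res$coefs[keep],
         y = y,
         treatment = data$treatment,
         cluster = data$cluster,
         time = data$time,
         engine = if (res$mixed) "mixed" else "glm",
         reml = reml,
         n = nrow(data),
         converged = res$converged),
    class = "crt_fit"
  )
}

#' @export
print.crt_fit <- function(x, ...) {
  cat(sprintf("<crt_fit> %s [%s/%s], engine=%s\n", x$spec$name, x$spec$family,
              x$spec$link, x$engine))
  cat(sprintf("  delta_hat = %.4f (SE %.4f); sigma2 = %.4f, tau2 = %.4f\n",
              x$delta_hat, x$se_hat, x$theta_hat$sigma2, x$theta_hat$tau2))
  invisible(x)
}

#' @rdname fit_nuisance
#' @param x A `crt_fit` object.
#' @param ... Unused.
#' @export
tidy.crt_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$spec$name,
    family = x$spec$family,
    estimate = x$delta_hat,
    std.error = x$se_hat,
    statistic = x$delta_hat / x$se_hat,
    sigma2 = x$theta_hat$sigma2,
    tau2 = x$theta_hat$tau2,
    engine = x$engine
  )
}

# Re-estimate the non-treatment fixed effects under the null: maximum
# likelihood with the treatment effect held at delta_star (an offset).
# Newton/Fisher scoring on the small design Xf; canonical links, so the two
# coincide. Warm starts keep this cheap inside the confidence-limit search.
null_fixed_effects <- function(fit, delta_star, start = NULL) {
  Xf <- fit$Xf
  off <- delta_star * fit$treatment
  y <- fit$y
  fam <- fit$spec$family
  if (fam == "gaussian") {
    beta <- drop(solve(crossprod(Xf), crossprod(Xf, y - off)))
  } else {
    linkinv <- fam_linkinv(fam)
    beta <- start %||% fit$Xf_beta
    for (it in seq_len(50L)) {
      eta <- drop(Xf %*% beta) + off
      mu <- linkinv(eta)
      w <- if (fam == "poisson") mu else pmax(mu * (1 - mu), 1e-10)
      step <- tryCatch(
        drop(solve(crossprod(Xf, Xf * w), crossprod(Xf, y - mu))),
        error = function(e) abort(
          sprintf("null refit for outcome '%s' is singular at delta* = %g",
                  fit$spec$name, delta_star),
          class = "permcrt_fit_error"))
      beta <- beta + step
      if (max(abs(step)) < 1e-8) break
    }
    if (any(!is.finite(beta)))
      abort(sprintf("null refit for outcome '%s' diverged at delta* = %g",
                    fit$spec$name, delta_star),
            class = "permcrt_fit_error")
  }
  list(eta = drop(Xf %*% beta), beta = beta)
}

#' Per-observation marginal means under a null treatment effect
#'
#' Returns `h(mu0 + delta_star * D + X beta)`, the marginal means under the
#' null hypothesis that the treatment effect equals `delta_star`. By default
#' the non-treatment fixed effects are re-estimated under that null (maximum
#' likelihood with the treatment term fixed at `delta_star`), which keeps the
#' studentized statistics of different outcomes comparable; they are then
#' frozen across all permutations. `refit = FALSE` instead plugs
#' `delta_star` into the unrestricted fit's linear predictor without
#' re-estimation.
#'
#' @param fit A `crt_fit` object.
#' @param data The `crt_data` the fit was produced from.
#' @param delta_star Null value of the treatment effect.
#' @param refit Re-estimate the non-treatment fixed effects under the null
#'   (default) or reuse the unrestricted estimates.
#' @return Numeric vector of means, one per observation.
#' @export
null_marginal_means <- function(fit, data, delta_star = 0, refit = TRUE) {
  if (!is.finite(delta_star))
    abort("delta_star must be finite", class = "permcrt_argument_error")
  if (nrow(data) != fit$n)
    abort("data does not match the fitted model", class = "permcrt_argument_error")
  linkinv <- fam_linkinv(fit$spec$family)
  eta0 <- if (refit) null_fixed_effects(fit, delta_star)$eta else fit$eta_base
  linkinv(eta0 + delta_star * data$treatment)
}

#' Build per-cluster covariance matrices and derivative weights
#'
#' Assembles, once per hypothesis family, the cluster covariance matrices
#' `V_c` implied by the fitted variance components, their inverses, and the
#' derivative weight vectors `G_c`; all are reused unchanged for every
#' permutation. For the exchangeable structure the diagonal is the family
#' variance at the null means plus `tau2` and off-diagonal elements are
#' `tau2` (for a Gaussian outcome: `sigma2 + tau2` and `tau2`). The
#' `ar_decay` structure correlates cluster-period effects across periods as
#' `tau2 * lambda^|t - t'|`.
#'
#' @param fit A `crt_fit` object.
#' @param data The matching `crt_data`.
#' @param delta_star Null value at which means (hence weights and variances)
#'   are evaluated.
#' @return An object of class `crt_covariance`: a list with per-cluster
#'   elements `V`, `Vinv`, `G`, and `rows` (row indices into `data`).
#' @export
build_cluster_covariance <- function(fit, data, delta_star = 0) {
  mu <- null_marginal_means(fit, data, delta_star)
  gw <- fam_gweight(fit$spec$family)(mu)
  vfun <- fam_variance(fit$spec$family)
  sigma2 <- fit$theta_hat$sigma2
  tau2 <- fit$theta_hat$tau2
  lambda <- fit$theta_hat$lambda
  if (fit$covariance == "ar_decay" && !is.finite(lambda))
    abort("ar_decay covariance requires a lambda value (supply via theta)",
          class = "permcrt_config_error")

  idx <- split(seq_len(nrow(data)), data$cluster, drop = TRUE)
  out <- lapply(names(idx), function(cl) {
    rows <- idx[[cl]]
    vdiag <- vfun(mu[rows], sigma2)
    n_c <- length(rows)
    V <- switch(fit$covariance,
      independence = diag(vdiag, n_c),
      exchangeable = {
        m <- matrix(tau2, n_c, n_c)
        diag(m) <- vdiag + tau2
        m
      },
      ar_decay = {
        tt <- data$time[rows]
        m <- tau2 * lambda^abs(outer(tt, tt, "-"))
        diag(m) <- vdiag + tau2
        m
      })
    Vinv <- tryCatch(chol2inv(chol(V)), error = function(e)
      abort(sprintf("covariance matrix for cluster '%s' is not positive definite", cl),
            class = "permcrt_numeric_error"))
    list(V = V, Vinv = Vinv, G = gw[rows], rows = rows)
  })
  names(out) <- names(idx)
  structure(out, class = "crt_covariance", outcome = fit$spec$name,
            delta_star = delta_star)
}
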