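# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small hand-built parallel trial: named list of per-cluster outcome
# vectors, character vector of treated cluster names.
tiny_trial <- function(y_by_cluster, treated, family = "gaussian") {
  df <- purrr::imap_dfr(y_by_cluster, function(y, cl)
    tibble::tibble(cluster = cl, y = y,
                   treatment = as.integer(cl %in% treated)))
  crt_data(df, outcomes = list(outcome_spec("y", family)),
           cluster = "cluster", treatment = "treatment")
}

# Synthetic crt_fit with known nuisance values (intercept-only linear
# predictor), bypassing model fitting; used to test the plug-in mean path
# and the permutation engine with known parameters.
make_fit <- function(data, name = "y", family = "gaussian", mu0 = 0,
                     delta_hat = 0, se_hat = 1, sigma2 = 1, tau2 = 0,
                     covariance = "exchangeable", lambda = NA_real_) {
  n <- nrow(data)
  structure(
    list(spec = outcome_spec(name, family),
         delta_hat = delta_hat, se_hat = se_hat,
         coefficients = c(`(Intercept)` = mu0, treatment = delta_hat),
         theta_hat = list(sigma2 = sigma2, tau2 = tau2, lambda = lambda),
         covariance = covariance,
         eta_base = rep(mu0, n),
         Xf = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
         Xf_beta = c(`(Intercept)` = mu0),
         y = data[[name]],
         treatment = data$treatment, cluster = data$cluster,
         time = data$time, engine = "glm", reml = FALSE,
         n = n, converged = TRUE),
    class = "crt_fit")
}

# Wrap a statistic matrix as a crt_perm object (for correction-level tests
# that do not need the data pipeline).
fake_perm <- function(observed, permuted, exact = FALSE,
                      sidedness = "two_sided") {
  J <- length(observed)
  nms <- names(observed) %||% paste0("y", seq_len(J))
  p_raw <- vapply(seq_len(J), function(j)
    mc_pvalue(observed[j], permuted[, j], sidedness, exact = exact),
    numeric(1))
  structure(list(observed = stats::setNames(observed, nms),
                 permuted = permuted,
                 p_raw = stats::setNames(p_raw, nms),
                 exact = exact, sidedness = sidedness, mode = "unweighted",
                 delta_star = stats::setNames(rep(0, J), nms)),
            class = "crt_perm")
}

# Independent brute-force stepdown oracle: explicitly forms the max
# statistic over every remaining subset at every step (apply-based, with a
# hand-rolled running maximum), never calling the package's stepdown.
rw_bruteforce <- function(observed, permuted, exact = FALSE) {
  J <- length(observed)
  L <- nrow(permuted)
  ord <- order(abs(observed), decreasing = TRUE)
  p_steps <- numeric(J)
  for (r in seq_len(J)) {
    subset_r <- ord[r:J]
    maxima <- apply(abs(permuted[, subset_r, drop = FALSE]), 1, max)
    cnt <- sum(maxima >= abs(observed[ord[r]]))
    p_steps[r] <- if (exact) cnt / L else (1 + cnt) / (L + 1)
  }
  running <- p_steps
  for (r in seq_len(J)[-1]) running[r] <- max(running[r], running[r - 1])
  out <- numeric(J)
  out[ord] <- running
  out
}

# Grid-inversion oracle for a single-outcome confidence interval: test a
# fine grid of null values with the exact enumeration test and return the
# sup/inf of the non-rejected region.
grid_ci_oracle <- function(trial, fit, alpha = 0.05, span = 4, by = 0.05) {
  grid <- seq(fit$delta_hat - span * fit$se_hat,
              fit$delta_hat + span * fit$se_hat, by = by * fit$se_hat)
  keep <- vapply(grid, function(d) {
    pr <- permutation_matrix(trial, list(fit), delta_star = d,
                             plan = permutation_plan(enumerate = TRUE))
    pr$p_raw[[1]] > alpha
  }, logical(1))
  range(grid[keep])
}

# Memoised simulation batches shared between acceptance-test blocks, so the
# main study conditions are simulated once per test run.
.batch_cache <- new.env(parent = emptyenv())
cached_batch <- function(key, expr) {
  if (!exists(key, envir = .batch_cache))
    assign(key, force(expr), envir = .batch_cache)
  get(key, envir = .batch_cache)
}
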