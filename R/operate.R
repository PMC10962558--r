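#' Estimate operating characteristics of the inference procedures
#'
#' Runs the full inference stack over simulated replicates of a scenario
#' and estimates, per correction method: the family-wise error rate (the
#' proportion of replicates rejecting at least one TRUE null, i.e. an
#' outcome with `delta_j = 0`), the family-wise coverage of the confidence
#' sets (simultaneous containment of every true effect), and mean interval
#' widths. The "naive" comparator is the model-based Wald test
#' `|delta_hat / SE| > z_{1-alpha/2}` with intervals
#' `delta_hat +/- z SE` and no correction.
#'
#' Replicate seeds are derived deterministically from `seed` (replicate `i`
#' uses `seed + i`), so runs are reproducible and can be partitioned.
#' Replicate-level failures (e.g. a degenerate fit) are logged and skipped
#' up to `max_failure_rate`.
#'
#' @param scenario A [crt_scenario()].
#' @param n_sims Number of simulation replicates.
#' @param methods Correction methods to score.
#' @param statistic `"unweighted"` or `"weighted"`.
#' @param include_naive Include the model-based Wald comparator.
#' @param ci_methods Methods for which confidence sets are searched (slow);
#'   default none.
#' @param M Permutations per replicate.
#' @param Q Search steps per confidence limit.
#' @param alpha Family-wise level.
#' @param seed Master integer seed.
#' @param engine Nuisance fitting engine; defaults to mixed models for
#'   single-period scenarios and fixed-effects GLMs for the multi-period
#'   scenario (where mixed software for autoregressive random effects is
#'   limited), with variance components then taken from the scenario.
#' @param max_failure_rate Abort if more than this fraction of replicates
#'   fail.
#' @return A tibble of class `crt_simsummary`: one row per method with
#'   `fwer`, `coverage`, `mean_width` (list column), Monte-Carlo standard
#'   errors, and `n_sims` completed.
#' @examples
#' \donttest{
#' sc <- crt_scenario(2, clusters_per_arm = 4)
#' run_scenario(sc, n_sims = 20, M = 99, seed = 1)
#' }
#' @export
run_scenario <- function(scenario, n_sims = 1000,
                         methods = c("romano_wolf", "holm", "bonferroni", "none"),
                         statistic = c("unweighted", "weighted"),
                         include_naive = TRUE, ci_methods = character(),
                         M = 500, Q = 1000, alpha = 0.05, seed = NULL,
                         engine = NULL, max_failure_rate = 0.1) {
  statistic <- match.arg(statistic)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(ci_methods %in% methods))
  seed <- seed %||% sample.int(1e6, 1)
  engine <- engine %||% if (scenario$model == 3L) "glm" else "auto"
  theta <- if (engine == "glm")
    list(tau2 = scenario$tau[1]^2, lambda = scenario$lambda)
  true_null <- scenario$delta == 0
  zcrit <- qnorm(1 - alpha / 2)

  all_methods <- c(methods, if (include_naive) "naive")
  rej <- matrix(NA, n_sims, length(all_methods),
                dimnames = list(NULL, all_methods))
  cover <- matrix(NA, n_sims, length(all_methods),
                  dimnames = list(NULL, all_methods))
  widths <- array(NA_real_, c(n_sims, length(all_methods), scenario$J),
                  dimnames = list(NULL, all_methods, paste0("y", seq_len(scenario$J))))
  failures <- 0L

  for (i in seq_len(n_sims)) {
    ok <- tryCatch({
      trial <- simulate_crt(scenario, seed = seed + i)
      fits <- suppressWarnings(lapply(outcome_specs(trial), function(sp)
        fit_nuisance(trial, sp, engine = engine, theta = theta)))
      perm <- permutation_matrix(trial, fits, delta_star = 0,
                                 plan = permutation_plan(M = M),
                                 mode = statistic)
      for (m in methods) {
        corr <- adjust_pvalues(perm, m, alpha)
        rej[i, m] <- any(corr$results$rejected[true_null])
        if (m %in% ci_methods) {
          ci <- crt_ci(trial, method = m, statistic = statistic,
                       alpha = alpha, Q = Q, fits = fits)
          cover[i, m] <- all(ci$results$lower <= scenario$delta &
                               scenario$delta <= ci$results$upper)
          widths[i, m, ] <- ci$results$upper - ci$results$lower
        }
      }
      if (include_naive) {
        # the naive comparator reads off default mixed-model output, which
        # for Gaussian outcomes means REML standard errors
        nfits <- lapply(outcome_specs(trial), function(sp) {
          if (sp$family == "gaussian" && engine != "glm")
            suppressWarnings(fit_nuisance(trial, sp, engine = engine,
                                          reml = TRUE, theta = theta))
          else fits[[sp$name]]
        })
        est <- vapply(nfits, `[[`, 0, "delta_hat")
        se <- vapply(nfits, `[[`, 0, "se_hat")
        z <- est / se
        rej[i, "naive"] <- any(abs(z[true_null]) > zcrit)
        cover[i, "naive"] <- all(abs(est - scenario$delta) <= zcrit * se)
        widths[i, "naive", ] <- 2 * zcrit * se
      }
      TRUE
    }, error = function(e) {
      inform(sprintf("replicate %d failed: %s", i, conditionMessage(e)))
      FALSE
    })
    if (!ok) {
      failures <- failures + 1L
      if (failures > max_failure_rate * n_sims)
        abort("too many replicate failures", class = "permcrt_simulation_error")
    }
  }

  prop <- function(x) mean(x, na.rm = TRUE)
  mc_se <- function(p, n) sqrt(p * (1 - p) / n)
  out <- purrr::map_dfr(all_methods, function(m) {
    done <- sum(!is.na(rej[, m]))
    fwer <- prop(rej[, m])
    cv <- if (any(!is.na(cover[, m]))) prop(cover[, m]) else NA_real_
    nc <- sum(!is.na(cover[, m]))
    tibble::tibble(
      method = m, statistic = if (m == "naive") NA_character_ else statistic,
      fwer = fwer, fwer_se = mc_se(fwer, done),
      coverage = cv, coverage_se = if (nc) mc_se(cv, nc) else NA_real_,
      mean_width = list(apply(widths[, m, , drop = FALSE], 3, prop)),
      n_sims = done
    )
  })
  structure(out, class = c("crt_simsummary", class(out)),
            scenario = scenario, alpha = alpha, seed = seed,
            failures = failures)
}

#' Tabulate simulation summaries with nominal-rate flags
#'
#' Combines one or more [run_scenario()] summaries into a results table,
#' flagging FWER and coverage cells lying within the approximate 95%
#' Monte-Carlo confidence interval of their nominal values (`alpha` and
#' `1 - alpha`).
#'
#' @param ... `crt_simsummary` objects (or a single list of them).
#' @return A tibble with per-outcome width columns and logical
#'   `fwer_nominal` / `coverage_nominal` flags.
#' @export
summarize_scenarios <- function(...) {
  summaries <- list(...)
  if (length(summaries) == 1L && !inherits(summaries[[1]], "crt_simsummary"))
    summaries <- summaries[[1]]
  alphas <- unique(vapply(summaries, attr, 0, "alpha"))
  stopifnot(length(alphas) == 1L)
  alpha <- alphas

  purrr::map_dfr(summaries, function(sm) {
    sc <- attr(sm, "scenario")
    class(sm) <- setdiff(class(sm), "crt_simsummary")
    wide <- sm |>
      dplyr::mutate(model = sc$model,
                    delta = paste0("(", paste(sc$delta, collapse = ","), ")"),
                    .before = 1) |>
      dplyr::mutate(
        fwer_nominal = abs(.data$fwer - alpha) <= 1.96 * .data$fwer_se,
        coverage_nominal = !is.na(.data$coverage) &
          abs(.data$coverage - (1 - alpha)) <= 1.96 * .data$coverage_se)
    w <- do.call(rbind, wide$mean_width)
    colnames(w) <- paste0("width_", colnames(w))
    dplyr::bind_cols(dplyr::select(wide, -"mean_width"),
                     tibble::as_tibble(w))
  })
}

#' @export
print.crt_simsummary <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<crt_simsummary> model %d, delta = (%s), %d replicates (%d failed)\n",
              sc$model, paste(sc$delta, collapse = ", "),
              max(x$n_sims), attr(x, "failures")))
  NextMethod()
}
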