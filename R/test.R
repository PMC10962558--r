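#' Permutation test of treatment effects with multiplicity correction
#'
#' One-stop analysis for a multi-outcome cluster randomized trial: fits the
#' univariate nuisance models, computes studentized quasi-score statistics
#' under the null values `delta_star`, builds the permutation distribution,
#' and returns raw and multiplicity-adjusted p-values.
#'
#' @param data A `crt_data` object.
#' @param outcomes Outcome declarations; defaults to those attached to
#'   `data`.
#' @param delta_star Null treatment-effect values (recycled across
#'   outcomes).
#' @param method Correction: `"romano_wolf"`, `"holm"`, `"bonferroni"`, or
#'   `"none"`.
#' @param statistic `"unweighted"` or `"weighted"` quasi-score statistic.
#' @param alpha Family-wise level.
#' @param M Number of Monte-Carlo permutations.
#' @param enumerate Enumerate the full allocation set when feasible.
#' @param sidedness `"two_sided"`, `"less"`, or `"greater"`.
#' @param seed Integer seed for the permutation stream.
#' @param engine,theta Passed to [fit_nuisance()].
#' @param fits Optional pre-computed list of `crt_fit` objects (skips
#'   refitting).
#' @return An object of class `crt_test` with a [tidy()] method giving one
#'   row per outcome (estimate, model SE, statistic, raw and adjusted
#'   p-value, rejection at `alpha`).
#' @examples
#' trial <- simulate_crt(crt_scenario(2, delta = c(0, 0.5)), seed = 7)
#' tt <- crt_test(trial, M = 199, seed = 1)
#' tidy(tt)
#' @export
crt_test <- function(data, outcomes = NULL, delta_star = 0,
                     method = c("romano_wolf", "holm", "bonferroni", "none"),
                     statistic = c("unweighted", "weighted"),
                     alpha = 0.05, M = 1000, enumerate = FALSE,
                     sidedness = c("two_sided", "less", "greater"),
                     seed = NULL, engine = "auto", theta = NULL,
                     fits = NULL) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  sidedness <- match.arg(sidedness)
  specs <- as_outcome_specs(outcomes %||% outcome_specs(data))
  fits <- fits %||% lapply(specs, function(sp)
    fit_nuisance(data, sp, engine = engine, theta = theta))
  plan <- permutation_plan(M = M, enumerate = enumerate, seed = seed,
                           sidedness = sidedness)
  perm <- permutation_matrix(data, fits, delta_star = delta_star,
                             plan = plan, mode = statistic)
  corr <- adjust_pvalues(perm, method, alpha)
  res <- corr$results |>
    dplyr::mutate(estimate = vapply(fits, `[[`, 0, "delta_hat"),
                  std.error = vapply(fits, `[[`, 0, "se_hat"),
                  .after = "outcome")
  structure(list(results = res, correction = corr, perm = perm, fits = fits,
                 alpha = alpha, method = method, statistic = statistic,
                 M = nrow(perm$permuted), seed = seed),
            class = "crt_test")
}

#' @export
print.crt_test <- function(x, ...) {
  cat(sprintf("<crt_test> %s correction, %s statistic, %d permutations, alpha=%g\n",
              x$method, x$statistic, x$M, x$alpha))
  print(x$results)
  invisible(x)
}

#' @rdname crt_test
#' @param x A `crt_test` object.
#' @param ... Unused.
#' @export
tidy.crt_test <- function(x, ...) x$results

#' @rdname crt_test
#' @export
glance.crt_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 n_outcomes = nrow(x$results), M = x$M, alpha = x$alpha,
                 exact = x$perm$exact,
                 n_rejected = sum(x$results$rejected))
}
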