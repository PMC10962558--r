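score_transform <- function(sidedness) {
  switch(sidedness, two_sided = abs, greater = identity,
         less = function(x) -x)
}

#' Multiplicity-adjusted p-values from a permutation result
#'
#' Applies one of four corrections to the raw per-outcome permutation
#' p-values: `none` (no correction), `bonferroni` (`min(J p_j, 1)`), `holm`
#' (ordered `(J - r + 1) p_(r)` with monotonicity enforcement), or
#' `romano_wolf` (resampling stepdown over max-statistics, see
#' [romano_wolf_stepdown()]). Bonferroni and Holm are computed with
#' [stats::p.adjust()] on the raw permutation p-values; Romano-Wolf uses the
#' full permuted statistic matrix and therefore adapts to the dependence
#' between outcomes.
#'
#' @param perm A `crt_perm` object from [permutation_matrix()].
#' @param method `"romano_wolf"`, `"holm"`, `"bonferroni"`, or `"none"`.
#' @param alpha Family-wise level for the rejection decisions.
#' @return An object of class `crt_correction`: list with `method`, `alpha`,
#'   `results` (tibble: outcome, statistic, p_raw, p_adj, rejected, step),
#'   and for Romano-Wolf the per-step estimated critical values.
#' @examples
#' trial <- simulate_crt(crt_scenario(2), seed = 1)
#' fits <- lapply(outcome_specs(trial), fit_nuisance, data = trial)
#' pr <- permutation_matrix(trial, fits, plan = permutation_plan(M = 199, seed = 1))
#' tidy(adjust_pvalues(pr, "romano_wolf"))
#' @export
adjust_pvalues <- function(perm,
                           method = c("romano_wolf", "holm", "bonferroni", "none"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (method == "romano_wolf") return(romano_wolf_stepdown(perm, alpha))
  p_raw <- perm$p_raw
  p_adj <- switch(method,
                  none = p_raw,
                  bonferroni = stats::p.adjust(p_raw, "bonferroni"),
                  holm = stats::p.adjust(p_raw, "holm"))
  g <- score_transform(perm$sidedness)
  res <- tibble::tibble(
    outcome = names(p_raw),
    statistic = unname(perm$observed),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    rejected = unname(p_adj <= alpha),
    step = rank(-g(unname(perm$observed)), ties.method = "first")
  )
  structure(list(method = method, alpha = alpha, results = res,
                 critical_values = NULL),
            class = "crt_correction")
}

#' Romano-Wolf resampling stepdown correction
#'
#' Orders the hypotheses by decreasing `|observed statistic|` and, at step
#' `r`, compares the `r`-th statistic with the permutation distribution of
#' the maximum statistic over the not-yet-rejected set `K_r`. The adjusted
#' p-value for the step is the (add-one Monte-Carlo, or exact enumeration)
#' proportion of these maxima at least as large as the observed value;
#' adjusted p-values are made monotone nondecreasing down the order, and
#' hypotheses are rejected while the adjusted p-value is at most `alpha`
#' (stepdown semantics: the first non-rejection stops the procedure). With a
#' single hypothesis the adjusted p-value equals the raw permutation
#' p-value. Ties in the ordering are broken by original outcome index.
#'
#' @inheritParams adjust_pvalues
#' @return A `crt_correction`; `critical_values` holds the estimated
#'   `c_K(1 - alpha)` per step (quantile index `ceiling(L (1 - alpha))`,
#'   clamped).
#' @export
romano_wolf_stepdown <- function(perm, alpha = 0.05) {
  g <- score_transform(perm$sidedness)
  tobs <- g(perm$observed)
  tperm <- g(perm$permuted)
  J <- length(tobs)
  L <- nrow(tperm)
  ord <- order(tobs, decreasing = TRUE)  # ties: original index

  p_step <- numeric(J)
  crit <- numeric(J)
  for (r in seq_len(J)) {
    K <- ord[r:J]
    maxs <- if (length(K) == 1L) tperm[, K] else
      do.call(pmax, as.data.frame(tperm[, K, drop = FALSE]))
    hits <- sum(maxs >= tobs[ord[r]])
    p_step[r] <- if (perm$exact) hits / L else (1 + hits) / (L + 1)
    qidx <- min(max(ceiling(L * (1 - alpha)), 1L), L)
    crit[r] <- sort(maxs, partial = qidx)[qidx]
  }
  p_step <- cummax(p_step)  # monotone along the stepdown order
  p_adj <- numeric(J)
  p_adj[ord] <- p_step
  rejected <- p_adj <= alpha

  res <- tibble::tibble(
    outcome = names(perm$observed),
    statistic = unname(perm$observed),
    p_raw = unname(perm$p_raw),
    p_adj = p_adj,
    rejected = rejected,
    step = match(seq_len(J), ord)
  )
  structure(list(method = "romano_wolf", alpha = alpha, results = res,
                 critical_values = stats::setNames(crit, names(perm$observed)[ord])),
            class = "crt_correction")
}

#' @export
print.crt_correction <- function(x, ...) {
  cat(sprintf("<crt_correction> method=%s, alpha=%g\n", x$method, x$alpha))
  print(x$results)
  invisible(x)
}

#' @rdname adjust_pvalues
#' @param x A `crt_correction` object.
#' @param ... Unused.
#' @export
tidy.crt_correction <- function(x, ...) {
  dplyr::mutate(x$results, method = x$method, .before = 1)
}
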