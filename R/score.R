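#' Signed treatment indicators for an allocation
#'
#' Expands a cluster-level allocation into the per-observation modified
#' intervention indicator `D*`, equal to +1 where the intervention is present
#' in that cluster-period and -1 otherwise. Clusters assigned to the treated
#' arm take the treated arm's observed treatment profile over time (all
#' periods in a parallel design; post-rollout periods only in a
#' baseline-period design), so baseline periods carry -1 for every cluster.
#'
#' @param data A `crt_data` object.
#' @param treated Character or factor vector of cluster labels assigned to
#'   the treated arm; defaults to the observed allocation.
#' @return Numeric vector of +1/-1, one per row of `data`.
#' @export
allocation_signs <- function(data, treated = NULL) {
  cp <- cluster_periods(data)
  obs_treated <- unique(as.character(cp$cluster[cp$treatment == 1L]))
  treated <- as.character(treated %||% obs_treated)
  if (length(treated) != length(obs_treated))
    abort("allocation must preserve the observed arm sizes",
          class = "permcrt_argument_error")
  # treatment-by-period profile of the treated arm (e.g. 0 then 1 under
  # rollout); must be shared by all treated clusters
  prof <- cp |>
    dplyr::filter(as.character(.data$cluster) %in% obs_treated) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(d = unique(.data$treatment), .groups = "drop")
  profile <- stats::setNames(prof$d, prof$time)
  d <- ifelse(as.character(data$cluster) %in% treated,
              profile[as.character(data$time)], 0L)
  2 * as.numeric(d) - 1
}

#' Per-cluster quasi-score contributions and studentized statistic
#'
#' Decomposes the quasi-score test statistic into one contribution per
#' cluster. In unweighted mode the contribution is the signed sum of
#' generalized residuals `sum_ti D*_ict (Y_ict - mu_ict)`; in weighted mode
#' residuals are first left-multiplied by `G_c V_c^-1`, weighting them in
#' proportion to their variance. The studentized total is the sum of
#' contributions divided by the root of their sum of squares.
#'
#' @param data A `crt_data` object.
#' @param outcome Outcome column name.
#' @param means Per-observation null means from [null_marginal_means()].
#' @param allocation Per-observation +1/-1 indicator from
#'   [allocation_signs()] (or a cluster-label vector of treated clusters).
#' @param mode `"unweighted"` or `"weighted"`.
#' @param cov A `crt_covariance` from [build_cluster_covariance()]; required
#'   in weighted mode, ignored otherwise.
#' @return A list of class `score_decomposition` with elements
#'   `contributions` (named per cluster), `statistic`, and `mode`.
#' @examples
#' trial <- simulate_crt(crt_scenario(1), seed = 1)
#' fit <- fit_nuisance(trial, outcome_specs(trial)$y1)
#' mu <- null_marginal_means(fit, trial, delta_star = 0)
#' sc <- score_contributions(trial, "y1", mu, allocation_signs(trial))
#' sc$statistic
#' @export
score_contributions <- function(data, outcome, means,
                                allocation,
                                mode = c("unweighted", "weighted"),
                                cov = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(allocation) || length(allocation) != nrow(data))
    allocation <- allocation_signs(data, allocation)
  if (length(means) != nrow(data))
    abort("means must have one value per observation",
          class = "permcrt_argument_error")
  r <- data[[outcome]] - means
  cl <- data$cluster
  contributions <- if (mode == "unweighted") {
    drop(rowsum(allocation * r, cl))
  } else {
    if (!inherits(cov, "crt_covariance"))
      abort("weighted mode requires a crt_covariance object",
            class = "permcrt_argument_error")
    vapply(cov, function(b) {
      drop((allocation[b$rows] * b$G) %*% b$Vinv %*% r[b$rows])
    }, numeric(1))
  }
  structure(list(contributions = contributions,
                 statistic = studentized_statistic(contributions),
                 mode = mode),
            class = "score_decomposition")
}

#' Studentized quasi-score statistic from cluster contributions
#'
#' Returns `sum(x) / sqrt(sum(x^2))`. Studentization makes the statistic
#' scale-free: without it, its variance depends on the null value being
#' tested, so different hypotheses would have unequal power and unbalanced
#' confidence sets. The statistic is antisymmetric under a global sign flip
#' of the allocation and bounded by `sqrt(C)` in absolute value.
#'
#' @param contributions Numeric vector of per-cluster contributions.
#' @return A scalar; 0 (with a warning) when every contribution is zero.
#' @examples
#' studentized_statistic(c(2, 0))  # 1
#' studentized_statistic(c(1, 1))  # sqrt(2)
#' @export
studentized_statistic <- function(contributions) {
  ss <- sum(contributions^2)
  if (ss == 0) {
    warn("all score contributions are zero; degenerate statistic")
    return(0)
  }
  sum(contributions) / sqrt(ss)
}
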