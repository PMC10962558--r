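#' Describe the permutation scheme
#'
#' @param M Number of Monte-Carlo permutations (ignored under enumeration).
#' @param enumerate Use the full allocation set when its size is at most
#'   `cap`; the identity allocation is then included exactly once and
#'   p-values are exact proportions rather than add-one estimates.
#' @param cap Largest allocation set that may be enumerated.
#' @param seed Integer seed for the Monte-Carlo allocation stream; `NULL`
#'   uses the current RNG state.
#' @param sidedness `"two_sided"`, `"less"`, or `"greater"`.
#' @param allocations Optional user-supplied list of treated cluster-label
#'   sets (e.g. from a restricted randomization scheme); overrides both
#'   enumeration and Monte-Carlo sampling.
#' @return A list of class `permutation_plan`.
#' @export
permutation_plan <- function(M = 1000, enumerate = FALSE, cap = 20000,
                             seed = NULL,
                             sidedness = c("two_sided", "less", "greater"),
                             allocations = NULL) {
  sidedness <- match.arg(sidedness)
  stopifnot(M >= 1)
  structure(list(M = as.integer(M), enumerate = enumerate, cap = cap,
                 seed = seed, sidedness = sidedness,
                 allocations = allocations),
            class = "permutation_plan")
}

#' Generate treatment re-allocations for the permutation group
#'
#' The permutation group acts on cluster(-period) treatment labels: an
#' allocation picks which clusters form the treated arm, always preserving
#' the observed arm sizes ("all ways of dividing the clusters into two
#' groups"). Enumeration returns every such division; Monte-Carlo sampling
#' draws allocations uniformly with replacement.
#'
#' @param data A `crt_data` object.
#' @param plan A [permutation_plan()].
#' @return A logical matrix with one row per allocation and one column per
#'   cluster (`TRUE` = assigned to the treated arm), with attribute `exact`
#'   indicating full enumeration.
#' @examples
#' trial <- simulate_crt(crt_scenario(2, clusters_per_arm = 3), seed = 1)
#' nrow(generate_allocations(trial, permutation_plan(enumerate = TRUE)))  # choose(6, 3)
#' @export
generate_allocations <- function(data, plan = permutation_plan()) {
  cp <- cluster_periods(data)
  arm <- cp |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(treated = any(.data$treatment == 1L), .groups = "drop")
  clusters <- as.character(arm$cluster)
  C <- length(clusters)
  k <- sum(arm$treated)
  if (k == 0L || k == C)
    abort("design has no between-arm contrast to permute",
          class = "permcrt_argument_error")

  if (!is.null(plan$allocations)) {
    S <- t(vapply(plan$allocations, function(a) clusters %in% as.character(a),
                  logical(C)))
    colnames(S) <- clusters
    if (!all(rowSums(S) == k))
      abort("user-supplied allocations must preserve arm sizes",
            class = "permcrt_argument_error")
    return(structure(S, exact = FALSE))
  }

  if (plan$enumerate) {
    L <- choose(C, k)
    if (L > plan$cap)
      abort(sprintf("full enumeration needs %d allocations (cap %d); use Monte Carlo",
                    L, plan$cap), class = "permcrt_argument_error")
    comb <- utils::combn(C, k)
    S <- matrix(FALSE, ncol(comb), C, dimnames = list(NULL, clusters))
    for (l in seq_len(ncol(comb))) S[l, comb[, l]] <- TRUE
    return(structure(S, exact = TRUE))
  }

  if (!is.null(plan$seed)) set.seed(plan$seed)
  S <- matrix(FALSE, plan$M, C, dimnames = list(NULL, clusters))
  for (m in seq_len(plan$M)) S[m, sample.int(C, k)] <- TRUE
  structure(S, exact = FALSE)
}

#' Monte-Carlo and enumeration permutation p-values
#'
#' For a two-sided test the Monte-Carlo estimate is
#' `(1 + #\{m : |T(a_m X)| >= |T(X)|\}) / (M + 1)`; one-sided tests use signed
#' comparisons. Ties count toward the numerator. Under full enumeration the
#' p-value is the exact proportion of the group (the identity allocation
#' guarantees it is positive).
#'
#' @param observed Observed statistic.
#' @param permuted Vector of permuted statistics.
#' @param sidedness `"two_sided"`, `"less"`, or `"greater"`.
#' @param exact `TRUE` when `permuted` is the full enumeration (identity
#'   included); `FALSE` for Monte-Carlo draws (add-one estimator).
#' @return A p-value in (0, 1].
#' @examples
#' mc_pvalue(2, rnorm(19))
#' @export
mc_pvalue <- function(observed, permuted,
                      sidedness = c("two_sided", "less", "greater"),
                      exact = FALSE) {
  sidedness <- match.arg(sidedness)
  if (!is.finite(observed) || any(!is.finite(permuted)))
    abort("nonfinite statistic", class = "permcrt_argument_error")
  hits <- switch(sidedness,
                 two_sided = abs(permuted) >= abs(observed),
                 greater = permuted >= observed,
                 less = permuted <= observed)
  if (exact) mean(hits) else (1 + sum(hits)) / (length(permuted) + 1)
}

# Precompute everything needed to evaluate the studentized statistic for any
# allocation at fixed residuals. For each cluster two per-observation weight
# vectors are formed: its contribution weights if assigned to the treated arm
# (carrying the treated arm's D* profile) and if assigned to control (all -1).
# Weighted mode folds G_c V_c^-1 into the weights, which are frozen with the
# nuisance fit.
score_engine <- function(data, fit, mode = "unweighted", cov = NULL) {
  N <- nrow(data)
  cl <- data$cluster
  clusters <- levels(cl)[table(cl) > 0]
  # D* per observation if its cluster held the treated arm's treatment
  # profile over time (vs all-control): +1 where treated, -1 otherwise
  cp <- cluster_periods(data)
  prof <- cp |>
    dplyr::filter(.data$treatment == 1L) |>
    dplyr::distinct(.data$time) |>
    dplyr::pull(.data$time)
  d_treat <- ifelse(data$time %in% prof, 1, -1)
  d_ctrl <- rep(-1, N)
  if (mode == "weighted") {
    if (!inherits(cov, "crt_covariance"))
      abort("weighted mode requires cluster covariance matrices",
            class = "permcrt_argument_error")
    wt <- numeric(N); wc <- numeric(N)
    for (b in cov) {
      wt[b$rows] <- drop(b$Vinv %*% (d_treat[b$rows] * b$G))
      wc[b$rows] <- drop(b$Vinv %*% (d_ctrl[b$rows] * b$G))
    }
  } else {
    wt <- d_treat; wc <- d_ctrl
  }
  Mind <- matrix(0, length(clusters), N, dimnames = list(clusters, NULL))
  Mind[cbind(match(as.character(cl), clusters), seq_len(N))] <- 1
  list(clusters = clusters, Mind = Mind, wt = wt, wc = wc)
}

# Studentized statistics for residual vector r under allocation matrix S
# (rows = allocations, cols = clusters, TRUE = treated arm).
engine_stats <- function(eng, r, S) {
  A <- drop(eng$Mind %*% (eng$wt * r))  # contribution if treated
  B <- drop(eng$Mind %*% (eng$wc * r))  # contribution if control
  num <- drop(S %*% (A - B)) + sum(B)
  den2 <- drop(S %*% (A^2 - B^2)) + sum(B^2)
  num / sqrt(den2)
}

observed_allocation <- function(data) {
  cp <- cluster_periods(data)
  arm <- cp |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(treated = any(.data$treatment == 1L), .groups = "drop")
  stats::setNames(arm$treated, as.character(arm$cluster))
}

#' Permuted statistic matrix and raw p-values for all outcomes
#'
#' Computes the observed studentized quasi-score statistics at the null
#' values `delta_star` and the full matrix of permuted statistics, holding
#' the generalized residuals `Y - mu_hat` and all nuisance quantities fixed
#' while the allocation signs vary.
#'
#' @param data A `crt_data` object.
#' @param fits List of `crt_fit` objects, one per outcome.
#' @param delta_star Numeric vector of null values (recycled across
#'   outcomes).
#' @param plan A [permutation_plan()].
#' @param mode `"unweighted"` or `"weighted"` statistic.
#' @param covs List of `crt_covariance` objects (weighted mode only); built
#'   automatically when omitted.
#' @return An object of class `crt_perm`: list with `observed` (named
#'   J-vector), `permuted` (L x J matrix), `p_raw`, `exact`, `sidedness`,
#'   `mode`.
#' @examples
#' trial <- simulate_crt(crt_scenario(2), seed = 1)
#' fits <- lapply(outcome_specs(trial), fit_nuisance, data = trial)
#' pr <- permutation_matrix(trial, fits, plan = permutation_plan(M = 99, seed = 1))
#' pr$p_raw
#' @export
permutation_matrix <- function(data, fits, delta_star = 0,
                               plan = permutation_plan(),
                               mode = c("unweighted", "weighted"),
                               covs = NULL) {
  mode <- match.arg(mode)
  J <- length(fits)
  nms <- vapply(fits, function(f) f$spec$name, "")
  names(fits) <- nms
  delta_star <- rep_len(delta_star, J)

  S <- generate_allocations(data, plan)
  exact <- isTRUE(attr(S, "exact"))
  obs <- observed_allocation(data)
  S_obs <- matrix(obs[colnames(S)], 1, ncol(S))

  if (mode == "weighted" && is.null(covs))
    covs <- lapply(seq_len(J), function(j)
      build_cluster_covariance(fits[[j]], data, delta_star[j]))

  observed <- stats::setNames(numeric(J), nms)
  permuted <- matrix(NA_real_, nrow(S), J, dimnames = list(NULL, nms))
  for (j in seq_len(J)) {
    fit <- fits[[j]]
    eng <- score_engine(data, fit, mode,
                        if (mode == "weighted") covs[[j]] else NULL)
    mu <- null_marginal_means(fit, data, delta_star[j])
    r <- data[[fit$spec$name]] - mu
    observed[j] <- engine_stats(eng, r, S_obs)
    permuted[, j] <- engine_stats(eng, r, S)
    if (!is.finite(observed[j]))
      abort(sprintf("nonfinite observed statistic for outcome '%s'", nms[j]),
            class = "permcrt_numeric_error")
    bad <- which(!is.finite(permuted[, j]))
    if (length(bad))
      abort(sprintf("nonfinite permuted statistic for outcome '%s' at permutation %d",
                    nms[j], bad[1]), class = "permcrt_numeric_error")
  }

  p_raw <- vapply(seq_len(J), function(j)
    mc_pvalue(observed[j], permuted[, j], plan$sidedness, exact = exact),
    numeric(1))
  structure(list(observed = observed, permuted = permuted,
                 p_raw = stats::setNames(p_raw, nms), exact = exact,
                 sidedness = plan$sidedness, mode = mode,
                 delta_star = stats::setNames(delta_star, nms)),
            class = "crt_perm")
}

#' @export
print.crt_perm <- function(x, ...) {
  cat(sprintf("<crt_perm> %d outcome(s), %d permutations (%s, %s)\n",
              length(x$observed), nrow(x$permuted),
              if (x$exact) "enumerated" else "Monte Carlo", x$mode))
  print(tibble::tibble(outcome = names(x$observed),
                       statistic = unname(x$observed),
                       p_raw = unname(x$p_raw)))
  invisible(x)
}
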