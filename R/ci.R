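#' Robbins-Monro step-length constant
#'
#' Evaluates `k = 2 z 1/sqrt(2 pi) exp(-z^2 / 2)` with
#' `z = qnorm(1 - alpha_star)`: twice the standard-normal quantile times the
#' normal density at that quantile. The step lengths of the confidence-limit
#' search are `s_j = k (u_j - delta_hat_j)` (upper) and
#' `k (delta_hat_j - l_j)` (lower).
#'
#' @param alpha_star Per-hypothesis test level in (0, 1).
#' @return The scalar step constant (0 at `alpha_star = 0.5`).
#' @examples
#' step_constant(0.05)  # ~0.3392
#' @export
step_constant <- function(alpha_star) {
  if (!is.numeric(alpha_star) || any(alpha_star <= 0) || any(alpha_star >= 1))
    abort("alpha_star must be in (0, 1)", class = "permcrt_argument_error")
  z <- qnorm(1 - alpha_star)
  2 * z * dnorm(z)
}

#' One Robbins-Monro update of a confidence limit
#'
#' Upper limits move down by `s * alpha_star / q` after a rejection and up
#' by `s * (1 - alpha_star) / q` otherwise; lower limits mirror this. The
#' `1/q` decay makes the recursion converge to the point where the
#' single-draw rejection probability equals `1 - alpha_star`, i.e. where the
#' permutation test at the limit has p-value `alpha_star`.
#'
#' @param bound Current limit.
#' @param s Step length (nonnegative).
#' @param alpha_star Per-hypothesis level.
#' @param q Iteration number (>= 1).
#' @param rejected Was the hypothesis at this limit rejected by the
#'   single-permutation comparison?
#' @param side `"upper"` or `"lower"`.
#' @return The updated limit.
#' @examples
#' update_bound(1, s = 0.3, alpha_star = 0.05, q = 4, rejected = TRUE, side = "upper")
#' @export
update_bound <- function(bound, s, alpha_star, q, rejected,
                         side = c("upper", "lower")) {
  side <- match.arg(side)
  stopifnot(q >= 1, s >= 0)
  delta <- if (rejected) -s * alpha_star / q else s * (1 - alpha_star) / q
  if (side == "lower") delta <- -delta
  bound + delta
}

# Per-hypothesis alpha* schedule in the stepdown order (position r of the
# ordering gets alpha/(J - r + 1) under Holm).
alpha_star_schedule <- function(method, alpha, J) {
  switch(method,
         none = , romano_wolf = rep(alpha, J),
         bonferroni = rep(alpha / J, J),
         holm = alpha / (J - seq_len(J) + 1))
}

# Single-draw rejection decisions given observed and one-permutation
# statistics (already on the comparison scale, larger = more extreme).
single_draw_rejections <- function(method, tobs, tperm) {
  J <- length(tobs)
  ord <- order(tobs, decreasing = TRUE)
  rej <- logical(J)
  if (method %in% c("none", "bonferroni")) {
    rej <- tperm < tobs
  } else if (method == "holm") {
    for (r in seq_len(J)) {
      j <- ord[r]
      if (tperm[j] < tobs[j]) rej[j] <- TRUE else break
    }
  } else { # romano_wolf: compare against max over the not-yet-rejected set
    for (r in seq_len(J)) {
      K <- ord[r:J]
      if (max(tperm[K]) < tobs[ord[r]]) rej[ord[r]] <- TRUE else break
    }
  }
  list(rejected = rej, order = ord)
}

#' Multiplicity-corrected confidence sets by stochastic approximation
#'
#' Locates the lower and upper limits of the simultaneous confidence set by
#' two independent Robbins-Monro searches. At step `q` the current limits
#' serve as the null values: the observed statistics are recomputed at those
#' nulls (nuisance estimates stay frozen), a single random re-allocation is
#' drawn, the chosen method's stepdown rule decides which hypotheses the
#' single draw rejects, and every limit takes one [update_bound()] step with
#' the method's per-hypothesis `alpha*` schedule (`alpha` for no correction
#' and Romano-Wolf, `alpha/J` for Bonferroni, `alpha/(J-r+1)` for Holm).
#' Searches start at `delta_hat_j +/- 2 SE_j` and run a fixed number of
#' steps; step lengths `k (u_jq - delta_hat_j)` are refreshed each iteration
#' and floored at a small positive fraction of the standard error so a limit
#' that crosses the point estimate cannot produce a negative step.
#'
#' @inheritParams crt_test
#' @param Q Number of search steps per limit (the paper-scale default is
#'   2000; longer runs are often needed for more outcomes).
#' @param k Optional override of the [step_constant()] value.
#' @param window,tol Convergence diagnostic settings, see
#'   [convergence_diagnostic()].
#' @return An object of class `crt_ci`: `results` (tibble with estimate,
#'   lower, upper, convergence flags), `trace` (long tibble: side,
#'   iteration, outcome, value), and the search settings. [autoplot()] draws
#'   the traces.
#' @examples
#' \donttest{
#' trial <- simulate_crt(crt_scenario(2), seed = 3)
#' ci <- crt_ci(trial, method = "romano_wolf", Q = 500, seed = 1)
#' tidy(ci)
#' }
#' @export
crt_ci <- function(data, outcomes = NULL,
                   method = c("romano_wolf", "holm", "bonferroni", "none"),
                   statistic = c("unweighted", "weighted"),
                   alpha = 0.05, Q = 2000, seed = NULL,
                   sidedness = c("two_sided", "less", "greater"),
                   engine = "auto", theta = NULL, fits = NULL, k = NULL,
                   window = 0.2, tol = 0.1) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  sidedness <- match.arg(sidedness)
  if (Q < 100) warn("fewer than 100 search steps; limits will be unreliable")
  specs <- as_outcome_specs(outcomes %||% outcome_specs(data))
  fits <- fits %||% lapply(specs, function(sp)
    fit_nuisance(data, sp, engine = engine, theta = theta))
  J <- length(fits)
  nms <- unname(vapply(fits, function(f) f$spec$name, ""))
  delta_hat <- vapply(fits, `[[`, 0, "delta_hat")
  se_hat <- vapply(fits, `[[`, 0, "se_hat")

  covs <- if (statistic == "weighted")
    lapply(fits, build_cluster_covariance, data = data, delta_star = 0)
  engines <- lapply(seq_len(J), function(j)
    score_engine(data, fits[[j]], statistic,
                 if (statistic == "weighted") covs[[j]] else NULL))
  linkinvs <- lapply(fits, function(f) fam_linkinv(f$spec$family))
  ys <- lapply(nms, function(nm) data[[nm]])
  D <- data$treatment
  g <- score_transform(sidedness)

  obs <- observed_allocation(data)
  clusters <- names(obs)
  C <- length(clusters)
  n_treat <- sum(obs)
  S_obs <- matrix(obs, 1, C)

  if (!is.null(seed)) set.seed(seed)
  side_seeds <- sample.int(.Machine$integer.max - 1L, 2)

  run_side <- function(side, side_seed) {
    set.seed(side_seed)
    b <- if (side == "upper") delta_hat + 2 * se_hat else delta_hat - 2 * se_hat
    trace <- matrix(NA_real_, Q, J, dimnames = list(NULL, nms))
    warm <- lapply(fits, `[[`, "Xf_beta")  # warm starts for the null refits
    for (q in seq_len(Q)) {
      trace[q, ] <- b
      tobs <- numeric(J); tperm <- numeric(J)
      S_q <- matrix(FALSE, 1, C)
      S_q[1, sample.int(C, n_treat)] <- TRUE
      for (j in seq_len(J)) {
        nf <- null_fixed_effects(fits[[j]], b[j], start = warm[[j]])
        warm[[j]] <- nf$beta
        mu <- linkinvs[[j]](nf$eta + b[j] * D)
        r <- ys[[j]] - mu
        tobs[j] <- engine_stats(engines[[j]], r, S_obs)
        tperm[j] <- engine_stats(engines[[j]], r, S_q)
      }
      dec <- single_draw_rejections(method, g(tobs), g(tperm))
      astar <- numeric(J)
      astar[dec$order] <- alpha_star_schedule(method, alpha, J)
      kq <- k %||% step_constant(astar)
      kq <- rep_len(kq, J)
      for (j in seq_len(J)) {
        s <- if (side == "upper") kq[j] * (b[j] - delta_hat[j])
             else kq[j] * (delta_hat[j] - b[j])
        s <- max(s, 0.05 * se_hat[j])
        b[j] <- update_bound(b[j], s, astar[j], q, dec$rejected[j], side)
      }
      if (any(!is.finite(b))) {
        bad <- nms[!is.finite(b)][1]
        abort(sprintf("confidence limit for '%s' became nonfinite at step %d (%s side)",
                      bad, q, side),
              class = "permcrt_numeric_error", trace = trace[seq_len(q), , drop = FALSE])
      }
    }
    list(bounds = b, trace = trace)
  }

  upper <- run_side("upper", side_seeds[1])
  lower <- run_side("lower", side_seeds[2])

  trace_tbl <- dplyr::bind_rows(
    tidyr::pivot_longer(
      tibble::as_tibble(upper$trace) |> dplyr::mutate(iteration = dplyr::row_number(), side = "upper"),
      cols = dplyr::all_of(nms), names_to = "outcome", values_to = "value"),
    tidyr::pivot_longer(
      tibble::as_tibble(lower$trace) |> dplyr::mutate(iteration = dplyr::row_number(), side = "lower"),
      cols = dplyr::all_of(nms), names_to = "outcome", values_to = "value")
  )

  width <- upper$bounds - lower$bounds
  conv <- convergence_diagnostic(trace_tbl, window = window, tol = tol,
                                 width = stats::setNames(width, nms))
  results <- tibble::tibble(
    outcome = nms,
    estimate = unname(delta_hat),
    std.error = unname(se_hat),
    lower = unname(lower$bounds),
    upper = unname(upper$bounds),
    converged_lower = conv$converged[match(paste(nms, "lower"),
                                           paste(conv$outcome, conv$side))],
    converged_upper = conv$converged[match(paste(nms, "upper"),
                                           paste(conv$outcome, conv$side))]
  )
  structure(list(results = results, trace = trace_tbl, diagnostics = conv,
                 method = method, statistic = statistic, alpha = alpha,
                 Q = Q, seed = seed),
            class = "crt_ci")
}

#' @export
print.crt_ci <- function(x, ...) {
  cat(sprintf("<crt_ci> %s correction, %s statistic, %d steps per limit, alpha=%g\n",
              x$method, x$statistic, x$Q, x$alpha))
  print(x$results)
  invisible(x)
}

#' @rdname crt_ci
#' @param x A `crt_ci` object.
#' @param ... Unused.
#' @export
tidy.crt_ci <- function(x, ...) x$results

#' @rdname crt_ci
#' @export
glance.crt_ci <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, alpha = x$alpha,
                 Q = x$Q, n_outcomes = nrow(x$results),
                 all_converged = all(x$results$converged_lower &
                                       x$results$converged_upper))
}

#' Convergence diagnostics for confidence-limit search traces
#'
#' A limit is flagged non-converged when, over the final `window` fraction
#' of its trace, either the range of visited values or the absolute linear
#' drift exceeds `tol` times the interval width. Convergence should also be
#' assessed graphically via [autoplot()]: a non-converged search typically
#' shows a late jump still decaying toward the limit.
#'
#' @param trace Long trace tibble with columns `side`, `iteration`,
#'   `outcome`, `value` (as produced by [crt_ci()]).
#' @param window Fraction of the trace tail to examine.
#' @param tol Tolerance as a fraction of the interval width.
#' @param width Named per-outcome interval widths used to scale `tol`; when
#'   `NULL`, the spread of each full trace is used instead.
#' @return A tibble: `outcome`, `side`, `range`, `drift`, `converged`.
#' @export
convergence_diagnostic <- function(trace, window = 0.2, tol = 0.1,
                                   width = NULL) {
  stopifnot(window > 0, window <= 1)
  trace |>
    dplyr::group_by(.data$outcome, .data$side) |>
    dplyr::group_modify(function(df, key) {
      Q <- nrow(df)
      tail_df <- df[df$iteration > (1 - window) * Q, ]
      w <- if (!is.null(width)) unname(width[key$outcome])
           else diff(range(df$value))
      w <- max(abs(w), .Machine$double.eps)
      rng <- diff(range(tail_df$value))
      slope <- if (nrow(tail_df) >= 2)
        unname(coef(stats::lm(value ~ iteration, data = tail_df))[2])
      else 0
      drift <- abs(slope) * nrow(tail_df)
      tibble::tibble(range = rng, drift = drift,
                     converged = rng <= tol * w & drift <= tol * w)
    }) |>
    dplyr::ungroup()
}

#' @rdname crt_ci
#' @param object A `crt_ci` object.
#' @export
autoplot.crt_ci <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$value,
                               colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "search step", y = "confidence limit",
                  colour = NULL,
                  title = sprintf("Confidence-limit search traces (%s)",
                                  object$method)) +
    ggplot2::theme_minimal()
}
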