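#' Plot the permutation null distributions
#'
#' Histograms of the permuted studentized statistics per outcome with the
#' observed statistic marked; a quick visual check of where the observed
#' values sit in their permutation distributions.
#'
#' @param object A `crt_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crt_test <- function(object, ...) {
  long <- tibble::as_tibble(object$perm$permuted) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "outcome",
                        values_to = "statistic")
  obs <- tibble::tibble(outcome = names(object$perm$observed),
                        statistic = unname(object$perm$observed))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$statistic),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "studentized statistic", y = "permutations",
                  title = sprintf("Permutation null distributions (%s)",
                                  object$statistic)) +
    ggplot2::theme_minimal()
}

#' Plot estimated operating characteristics
#'
#' Dot plot of FWER (and coverage where available) by method with
#' approximate 95% Monte-Carlo intervals and the nominal rate marked.
#'
#' @param object A `crt_simsummary` from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crt_simsummary <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- dplyr::bind_rows(
    tibble::tibble(metric = "FWER", method = object$method,
                   value = object$fwer, se = object$fwer_se,
                   nominal = alpha),
    tibble::tibble(metric = "Coverage", method = object$method,
                   value = object$coverage, se = object$coverage_se,
                   nominal = 1 - alpha)
  ) |> dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$nominal),
                        linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - 1.96 * .data$se,
                                          ymax = .data$value + 1.96 * .data$se)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
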