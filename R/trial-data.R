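#' Declare an outcome and its model family
#'
#' Each outcome analysed in a multi-outcome cluster trial is declared with a
#' distribution family, a link function, and the covariate terms entering its
#' linear predictor. Only the canonical family-link pairs are supported:
#' gaussian/identity, poisson/log, bernoulli/logit.
#'
#' @param name Name of the outcome column.
#' @param family One of `"gaussian"`, `"poisson"`, `"bernoulli"`.
#' @param link Link function; if `NULL` the canonical link for `family` is
#'   used (`identity`, `log`, `logit` respectively).
#' @param covariates Character vector of covariate column names entering the
#'   linear predictor (temporal fixed effects are added automatically for
#'   multi-period designs).
#'
#' @return An object of class `outcome_spec`.
#' @examples
#' outcome_spec("y1", "poisson")
#' outcome_spec("y2", "gaussian", covariates = "age")
#' @export
outcome_spec <- function(name,
                         family = c("gaussian", "poisson", "bernoulli"),
                         link = NULL,
                         covariates = character()) {
  family <- match.arg(family)
  canonical <- c(gaussian = "identity", poisson = "log", bernoulli = "logit")
  link <- link %||% unname(canonical[family])
  if (!identical(link, unname(canonical[family]))) {
    abort(sprintf("unsupported family-link pair: %s/%s", family, link),
          class = "permcrt_config_error")
  }
  stopifnot(is.character(name), length(name) == 1L)
  structure(
    list(name = name, family = family, link = link,
         covariates = as.character(covariates)),
    class = "outcome_spec"
  )
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf("<outcome_spec> %s: %s(%s)", x$name, x$family, x$link))
  if (length(x$covariates))
    cat(" +", paste(x$covariates, collapse = " + "))
  cat("\n")
  invisible(x)
}

as_outcome_specs <- function(outcomes) {
  if (inherits(outcomes, "outcome_spec")) outcomes <- list(outcomes)
  if (is.character(outcomes)) outcomes <- lapply(outcomes, outcome_spec)
  if (!is.list(outcomes) || !all(vapply(outcomes, inherits, TRUE, "outcome_spec")))
    abort("`outcomes` must be outcome_spec objects or outcome column names",
          class = "permcrt_config_error")
  names(outcomes) <- vapply(outcomes, `[[`, "", "name")
  outcomes
}

#' Assemble and validate multi-outcome cluster-trial data
#'
#' Takes a long-format data frame (one row per individual observation) and
#' returns a validated trial dataset: canonical `cluster`, `time`, and
#' `treatment` columns plus the declared outcome and covariate columns.
#' Treatment must be binary and constant within each cluster-period, and the
#' mapped columns must be free of missing values (or rows are dropped when
#' `na_action = "drop"`).
#'
#' @param data A data frame in long format.
#' @param outcomes Outcome declarations: a list of [outcome_spec()] objects
#'   (or a character vector of Gaussian outcome names).
#' @param cluster,treatment,time,id Names of the columns holding the cluster
#'   label, the 0/1 treatment indicator, the integer time period, and the
#'   individual label. `time = NULL` declares a single-period design;
#'   `id = NULL` numbers rows within cluster-period.
#' @param covariates Character vector of covariate columns to retain.
#' @param na_action `"fail"` (default) errors on missing values in mapped
#'   columns; `"drop"` removes the offending rows and reports the count.
#'
#' @return A tibble of class `crt_data` with attributes `outcomes` and
#'   `covariates`.
#' @examples
#' df <- data.frame(clinic = rep(1:4, each = 5),
#'                  arm = rep(c(0, 1), each = 10),
#'                  score = rnorm(20))
#' trial <- crt_data(df, outcomes = "score", cluster = "clinic",
#'                   treatment = "arm")
#' @export
crt_data <- function(data, outcomes, cluster = "cluster",
                     treatment = "treatment", time = NULL, id = NULL,
                     covariates = character(),
                     na_action = c("fail", "drop")) {
  na_action <- match.arg(na_action)
  specs <- as_outcome_specs(outcomes)
  data <- tibble::as_tibble(data)

  needed <- c(cluster, treatment, time, id, covariates, names(specs),
              unique(unlist(lapply(specs, `[[`, "covariates"))))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    abort(paste0("column(s) not found in data: ",
                 paste(missing_cols, collapse = ", ")),
          class = "permcrt_config_error")
  covariates <- union(covariates,
                      unlist(lapply(specs, `[[`, "covariates")))

  out <- tibble::tibble(
    cluster = factor(data[[cluster]]),
    time = if (is.null(time)) 1L else as.integer(data[[time]]),
    individual = if (is.null(id)) NA_character_ else as.character(data[[id]]),
    treatment = data[[treatment]]
  )
  for (cv in covariates) out[[cv]] <- data[[cv]]
  for (nm in names(specs)) out[[nm]] <- data[[nm]]

  mapped <- c("cluster", "time", "treatment", covariates, names(specs))
  bad <- !stats::complete.cases(out[mapped])
  if (any(bad)) {
    if (na_action == "fail")
      abort(sprintf("%d row(s) contain missing values in mapped columns", sum(bad)),
            class = "permcrt_validation_error")
    inform(sprintf("dropped %d row(s) with missing values", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  if (anyNA(out$individual)) {
    out <- out |>
      dplyr::group_by(.data$cluster, .data$time) |>
      dplyr::mutate(individual = as.character(dplyr::row_number())) |>
      dplyr::ungroup()
  }

  if (!all(out$treatment %in% c(0, 1)))
    abort("treatment indicator must be binary 0/1",
          class = "permcrt_validation_error")
  out$treatment <- as.integer(out$treatment)

  varying <- out |>
    dplyr::group_by(.data$cluster, .data$time) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$treatment), .groups = "drop") |>
    dplyr::filter(.data$k > 1L)
  if (nrow(varying))
    abort(paste0("treatment varies within cluster-period(s): ",
                 paste(sprintf("%s/t=%d", varying$cluster, varying$time),
                       collapse = ", ")),
          class = "permcrt_validation_error")

  for (sp in specs) {
    y <- out[[sp$name]]
    if (sp$family == "poisson" && (any(y < 0) || any(y != round(y))))
      abort(sprintf("outcome '%s' declared poisson but is not a nonnegative integer count",
                    sp$name), class = "permcrt_validation_error")
    if (sp$family == "bernoulli" && !all(y %in% c(0, 1)))
      abort(sprintf("outcome '%s' declared bernoulli but is not 0/1", sp$name),
            class = "permcrt_validation_error")
  }

  structure(out,
            class = c("crt_data", class(tibble::tibble())),
            outcomes = specs, covariates = covariates)
}

#' @export
print.crt_data <- function(x, ...) {
  specs <- attr(x, "outcomes")
  cat(sprintf("<crt_data> %d observations, %d clusters, %d period(s), %d outcome(s)\n",
              nrow(x), nlevels(x$cluster), length(unique(x$time)), length(specs)))
  cat("outcomes:", paste(vapply(specs, function(s) sprintf("%s [%s]", s$name, s$family), ""),
                         collapse = ", "), "\n")
  NextMethod()
}

#' Outcome declarations attached to a trial dataset
#' @param data A `crt_data` object.
#' @return Named list of [outcome_spec()] objects.
#' @export
outcome_specs <- function(data) attr(data, "outcomes")

#' Cluster-period summary of a trial dataset
#'
#' One row per (cluster, period) with its treatment indicator and size; this
#' is the level at which treatment is defined and at which the permutation
#' group acts.
#'
#' @param data A `crt_data` object.
#' @return A tibble with columns `cluster`, `time`, `treatment`, `n`.
#' @export
cluster_periods <- function(data) {
  data |>
    dplyr::group_by(.data$cluster, .data$time) |>
    dplyr::summarise(treatment = .data$treatment[1], n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$cluster, .data$time)
}

#' Read a delimited trial table from disk
#'
#' Reads comma- or tab-delimited text with a header row and validates it via
#' [crt_data()]. The delimiter is taken from the file extension (`.csv` comma,
#' otherwise tab) unless given explicitly.
#'
#' @param path Path to the delimited file.
#' @param outcomes,cluster,treatment,time,id,covariates,na_action Passed to
#'   [crt_data()].
#' @param delim Field delimiter; `NULL` to infer from the extension.
#' @return A validated `crt_data` tibble.
#' @export
read_trial_table <- function(path, outcomes, cluster = "cluster",
                             treatment = "treatment", time = NULL, id = NULL,
                             covariates = character(), delim = NULL,
                             na_action = c("fail", "drop")) {
  delim <- delim %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  crt_data(raw, outcomes = outcomes, cluster = cluster, treatment = treatment,
           time = time, id = id, covariates = covariates,
           na_action = na_action)
}

#' Write a trial dataset as delimited text
#'
#' @param data A `crt_data` object (or plain data frame).
#' @param path Output path; `.csv` writes comma-delimited, anything else tab.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  df <- as.data.frame(data)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Define the family of null hypotheses to test
#'
#' @param null_values Numeric vector of null treatment-effect values, one per
#'   outcome (recycled from length 1).
#' @param alpha Family-wise level in (0, 1).
#' @param sidedness `"two_sided"`, `"less"`, or `"greater"`.
#' @return A list of class `hypothesis_set`.
#' @export
hypothesis_set <- function(null_values = 0, alpha = 0.05,
                           sidedness = c("two_sided", "less", "greater")) {
  sidedness <- match.arg(sidedness)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    abort("alpha must be in (0, 1)", class = "permcrt_config_error")
  if (!all(is.finite(null_values)))
    abort("null_values must be finite", class = "permcrt_config_error")
  structure(list(null_values = null_values, alpha = alpha,
                 sidedness = sidedness),
            class = "hypothesis_set")
}
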