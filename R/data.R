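#' Build a validated dose-response table
#'
#' Validates a raw table of replicated dose-response observations and returns
#' a `dose_response` tibble: one row per experimental unit with a non-negative
#' `dose` (the untreated control is dose 0), a finite non-negative `response`
#' (e.g. root length in mm), an optional `replicate` label, and a `weight`
#' column (1 until [compute_weights()] is applied). Per-dose summaries are
#' available through [dose_summaries()].
#'
#' Dose levels that differ only by floating-point noise (relative tolerance
#' 1e-9) are merged onto their first representative. Designs need at least 5
#' distinct dose levels including an untreated control at dose 0; the control
#' mean anchors starting values downstream.
#'
#' @param data A data frame with at least the dose and response columns.
#' @param dose,response,replicate Column names (tidy-select style strings or
#'   bare names) holding the dose, the response, and an optional replicate id.
#' @return A tibble of class `dose_response` with columns `dose`, `response`,
#'   `replicate`, `weight`. Row order of the input is preserved.
#' @seealso [read_dose_response()], [compute_weights()], [dose_summaries()]
#' @export
#' @examples
#' d <- data.frame(dose = rep(c(0, 1, 3, 10, 30), each = 3),
#'                 response = rnorm(15, 50, 2))
#' dose_response(d)
dose_response <- function(data, dose = "dose", response = "response",
                          replicate = NULL) {
  dose_col <- rlang::as_name(rlang::enquo(dose))
  resp_col <- rlang::as_name(rlang::enquo(response))
  rep_quo <- rlang::enquo(replicate)
  rep_col <- if (rlang::quo_is_null(rep_quo)) NULL else rlang::as_name(rep_quo)

  for (col in c(dose_col, resp_col, rep_col)) {
    if (!col %in% names(data)) {
      hf_abort(sprintf("Column `%s` not found in the input table.", col),
               "schema_error")
    }
  }

  x <- as.numeric(data[[dose_col]])
  y <- as.numeric(data[[resp_col]])
  if (anyNA(x) || any(!is.finite(x))) {
    hf_abort("All doses must be finite numbers.", "validation_error")
  }
  bad <- which(x < 0)
  if (length(bad) > 0) {
    hf_abort(sprintf("Negative dose at row(s) %s.",
                     paste(head(bad, 5), collapse = ", ")),
             "validation_error", rows = bad)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    bad <- which(!is.finite(y))
    hf_abort(sprintf("Non-finite response at row(s) %s.",
                     paste(head(bad, 5), collapse = ", ")),
             "validation_error", rows = bad)
  }

  # merge dose levels equal up to relative tolerance 1e-9
  lev <- sort(unique(x))
  if (length(lev) > 1) {
    keep <- c(TRUE, diff(lev) > 1e-9 * pmax(abs(lev[-1]), 1))
    canon <- lev[keep]
    x <- canon[vapply(x, function(v) which.min(abs(canon - v)), integer(1))]
  }

  levels <- sort(unique(x))
  if (length(levels) < 5) {
    hf_abort(sprintf("Need at least 5 distinct dose levels, got %d.",
                     length(levels)),
             "design_error")
  }
  if (min(levels) != 0) {
    hf_abort("An untreated control (dose 0) is required.", "design_error")
  }

  out <- tibble(
    dose = x,
    response = y,
    replicate = if (is.null(rep_col)) NA_character_ else
      as.character(data[[rep_col]]),
    weight = 1
  )
  class(out) <- c("dose_response", class(out))
  attr(out, "weight_scheme") <- "none"
  out
}

#' Read a dose-response CSV
#'
#' Reads a CSV with one row per experimental unit and validates it with
#' [dose_response()]. The file must have a header; columns may be remapped
#' via `dose`, `response`, `replicate`.
#'
#' @param path Path to a CSV file (UTF-8, decimal point).
#' @inheritParams dose_response
#' @return A `dose_response` tibble.
#' @export
read_dose_response <- function(path, dose = "dose", response = "response",
                               replicate = NULL) {
  if (!file.exists(path)) {
    hf_abort(sprintf("File not found: %s", path), "schema_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dose_response(raw, dose = {{ dose }}, response = {{ response }},
                replicate = {{ replicate }})
}

#' Per-dose summaries of a dose-response table
#'
#' @param data A `dose_response` tibble (or any table with `dose`, `response`
#'   and optionally `weight` columns).
#' @return A tibble with one row per dose level, sorted by increasing dose:
#'   `dose`, `n`, `mean`, `sd` (NA when n = 1), `weight` (the per-observation
#'   weight at that dose).
#' @export
dose_summaries <- function(data) {
  data |>
    dplyr::group_by(dose = .data$dose) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$response),
      sd = stats::sd(.data$response),
      weight = if ("weight" %in% names(data)) .data$weight[1] else 1,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$dose)
}

#' Attach variance-stabilizing weights
#'
#' Computes per-observation regression weights from the replicate spread at
#' each dose level, the scheme used to stabilise response variance before
#' weighted nonlinear least squares. `inverse_sd` (the default) sets the
#' weight to 1/SD of the replicates at the observation's dose; the weighted
#' objective downstream is \eqn{\sum_i w_i (y_i - \mu(x_i))^2}.
#' `inverse_variance` uses 1/SD^2; `none` sets all weights to 1.
#'
#' A dose level whose replicates have zero spread would get infinite weight;
#' by default (`zero_sd_fallback = TRUE`) its SD is replaced by the smallest
#' positive per-dose SD (with a message). With the fallback disabled this is
#' an error.
#'
#' @param data A `dose_response` tibble.
#' @param scheme One of `"inverse_sd"`, `"inverse_variance"`, `"none"`.
#' @param zero_sd_fallback Replace zero per-dose SDs by the minimum positive
#'   per-dose SD instead of erroring.
#' @return The input with its `weight` column replaced; weights are constant
#'   within a dose level.
#' @export
compute_weights <- function(data, scheme = c("inverse_sd", "inverse_variance",
                                             "none"),
                            zero_sd_fallback = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "none") {
    data$weight <- 1
    attr(data, "weight_scheme") <- "none"
    return(data)
  }
  summ <- dose_summaries(data)
  if (any(summ$n < 2)) {
    hf_abort(sprintf(
      "Scheme '%s' needs >= 2 replicates at every dose; dose(s) %s have 1.",
      scheme, paste(summ$dose[summ$n < 2], collapse = ", ")),
      "insufficient_replication")
  }
  sds <- summ$sd
  zero <- sds <= 0
  if (any(zero)) {
    if (!zero_sd_fallback || all(zero)) {
      hf_abort(sprintf(
        "Zero replicate SD at dose(s) %s and fallback disabled.",
        paste(summ$dose[zero], collapse = ", ")),
        "degenerate_variance")
    }
    fallback <- min(sds[!zero])
    rlang::inform(sprintf(
      "Replacing zero replicate SD at dose(s) %s by fallback SD %g.",
      paste(summ$dose[zero], collapse = ", "), fallback))
    sds[zero] <- fallback
  }
  w_per_dose <- if (scheme == "inverse_sd") 1 / sds else 1 / sds^2
  data$weight <- w_per_dose[match(data$dose, summ$dose)]
  attr(data, "weight_scheme") <- scheme
  data
}

#' Write per-dose summaries to CSV
#'
#' @param data A `dose_response` tibble.
#' @param path Output path.
#' @return The summary tibble, invisibly.
#' @export
write_dose_summaries <- function(data, path) {
  summ <- dose_summaries(data)
  readr::write_csv(summ, path)
  invisible(summ)
}
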