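#' Tidy a hormetic fit
#'
#' One row per free parameter with estimate, standard error and t
#' confidence interval from the fit covariance.
#'
#' @param x A `hormesis_fit`.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @method tidy hormesis_fit
#' @export
tidy.hormesis_fit <- function(x, conf.level = 0.95, ...) {
  terms <- names(x$estimates)
  if (is.null(x$vcov)) {
    return(tibble(term = terms, estimate = unname(x$estimates),
                  std.error = NA_real_, conf.low = NA_real_,
                  conf.high = NA_real_))
  }
  purrr::map_dfr(terms, function(tm) {
    ci <- wald_ci(x, tm, level = conf.level)
    tibble(term = tm, estimate = ci$estimate, std.error = ci$se,
           conf.low = ci$lower, conf.high = ci$upper)
  })
}

#' Glance at a hormetic fit
#'
#' @param x A `hormesis_fit`.
#' @param ... Unused.
#' @return One-row tibble: family, kind, `ss_res`, `df_res`,
#'   `ss_res_over_df`, `pseudo_r2`, `nobs`, `n_free`, `converged`,
#'   `n_iter`.
#' @method glance hormesis_fit
#' @export
glance.hormesis_fit <- function(x, ...) {
  tibble(family = x$family, kind = x$model$kind,
         ss_res = x$ss_res, df_res = x$df_res,
         ss_res_over_df = x$ss_res / x$df_res,
         pseudo_r2 = 1 - x$ss_res / x$ss_corrected,
         nobs = nrow(x$data), n_free = length(x$estimates),
         converged = x$converged, n_iter = x$n_iter)
}

#' Augment data with fitted values and residuals
#'
#' @param x A `hormesis_fit`.
#' @param ... Unused.
#' @return The fitting data with `.fitted` and `.resid` columns appended,
#'   in the original row order.
#' @method augment hormesis_fit
#' @export
augment.hormesis_fit <- function(x, ...) {
  out <- as_tibble(x$data)
  out$.fitted <- x$fitted
  out$.resid <- x$residuals
  out
}
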