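#' Effective-dose estimates with standard errors and intervals
#'
#' Estimates the requested effective doses for a fitted hormetic model. The
#' default route (`source = "direct_reparam_fit"`) refits the corresponding
#' reparameterized model for each target — ED_K, LDS, and M become free
#' parameters — starting from the natural fit's own optimum, so the refit
#' reaches the identical curve and weighted SS_res and the target dose gets
#' a standard error and t confidence interval straight from the refit
#' covariance. `source = "delta_from_natural"` instead extracts each dose
#' from the natural fit by the numeric oracle
#' ([effective_doses_numeric()]) and propagates the covariance by the delta
#' method; the two routes agree closely on well-conditioned fits and the
#' pair is the package's internal cross-validation.
#'
#' @param fit A natural-parameter `hormesis_fit` (BC or CRS; for the
#'   monotone log-logistic only ED_K targets are meaningful).
#' @param K Percent-inhibition levels for ED_K rows, default 50.
#' @param quantities Which quantities to report, subset of
#'   `c("ED", "LDS", "M", "y_max")`.
#' @param convention ED_K convention, see [target_quantity()].
#' @param level Confidence level.
#' @param source `"direct_reparam_fit"` (default) or `"delta_from_natural"`.
#' @return A tibble: `quantity`, `K`, `estimate`, `se`, `lower`, `upper`,
#'   `df`, `source`, `convention`, plus `ss_res` of the refit for the direct
#'   route.
#' @export
#' @examples
#' set.seed(4)
#' d <- compute_weights(simulate_dose_response())
#' fit <- fit_hormesis(d, "cedergreen", a = 1)
#' effective_doses(fit, K = c(10, 50, 90))
effective_doses <- function(fit, K = 50,
                            quantities = c("ED", "LDS", "M", "y_max"),
                            convention = c("relative_to_control",
                                           "relative_to_range"),
                            level = 0.95,
                            source = c("direct_reparam_fit",
                                       "delta_from_natural")) {
  stopifnot(inherits(fit, "hormesis_fit"))
  if (fit$model$kind != "natural") {
    hf_abort("`effective_doses()` expects a natural-parameter fit.",
             "value_error")
  }
  quantities <- match.arg(quantities, several.ok = TRUE)
  convention <- match.arg(convention)
  source <- match.arg(source)
  hormetic <- fit$family != "loglogistic4"
  if (!hormetic) quantities <- intersect(quantities, "ED")

  np <- hm_natural_params(fit)
  oracle <- effective_doses_numeric(fit$family, np,
                                    K = if ("ED" %in% quantities) K else
                                      numeric(0),
                                    convention = convention)
  targets <- list()
  if ("M" %in% quantities) targets <- c(targets, list(target_quantity("M")))
  if ("LDS" %in% quantities) targets <- c(targets, list(target_quantity("LDS")))
  if ("ED" %in% quantities) {
    targets <- c(targets, lapply(K, function(k)
      target_quantity("ED_K", K = k, convention = convention)))
  }

  rows <- purrr::map_dfr(targets, function(tg) {
    tname <- switch(tg$kind, ED_K = "ED_K", LDS = "LDS", M = "M")
    val <- if (tg$kind == "ED_K") {
      oracle$value[oracle$quantity == "ED_K" & oracle$K == tg$K]
    } else {
      oracle$value[oracle$quantity == tg$kind]
    }
    if (source == "direct_reparam_fit") {
      spec <- build_reparam_model(fit$family, tg)
      start <- c(np[setdiff(spec$par_names, tname)], setNames(val, tname))
      a_arg <- if ("a" %in% names(fit$fixed)) unname(fit$fixed["a"]) else
        "free"
      refit <- fit_hormesis(fit$data, spec, start = start, a = a_arg,
                            control = fit$control)
      ci <- wald_ci(refit, tname, level = level)
      tibble(quantity = tg$kind, K = if (tg$kind == "ED_K") tg$K else
               NA_real_,
             estimate = ci$estimate, se = ci$se, lower = ci$lower,
             upper = ci$upper, df = ci$df, source = source,
             convention = tg$convention, ss_res = refit$ss_res)
    } else {
      g <- function(par) {
        full <- c(par, fit$fixed)
        res <- effective_doses_numeric(fit$family, full,
                                       K = if (tg$kind == "ED_K") tg$K else
                                         numeric(0),
                                       convention = convention)
        if (tg$kind == "ED_K") res$value[res$quantity == "ED_K"] else
          res$value[res$quantity == tg$kind]
      }
      se <- hf_delta_se(fit, g)
      tq <- qt((1 + level) / 2, df = fit$df_res)
      tibble(quantity = tg$kind, K = if (tg$kind == "ED_K") tg$K else
               NA_real_,
             estimate = val, se = se, lower = val - tq * se,
             upper = val + tq * se, df = fit$df_res, source = source,
             convention = tg$convention, ss_res = NA_real_)
    }
  })

  if ("y_max" %in% quantities && hormetic) {
    ym <- y_max_estimate(fit, level = level)
    rows <- dplyr::bind_rows(rows, tibble(
      quantity = ym$quantity, K = NA_real_, estimate = ym$estimate,
      se = ym$se, lower = ym$lower, upper = ym$upper, df = fit$df_res,
      source = "delta_from_natural", convention = convention,
      ss_res = NA_real_))
  }
  rows
}

#' Write an effective-dose table to CSV
#'
#' @param ed_table Output of [effective_doses()].
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_effective_doses <- function(ed_table, path) {
  readr::write_csv(ed_table, path)
  invisible(ed_table)
}
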