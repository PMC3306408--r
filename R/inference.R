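# Wald/t inference on fitted hormetic models: parameter confidence
# intervals, the CI-excludes-zero test for the significance of hormesis,
# delta-method prediction (used for y_max at x = M), and quantification of
# a pre-hormetic drop of the CRS curve.

#' Wald/t confidence interval for a fitted parameter
#'
#' `estimate +/- t(df_res, (1 + level)/2) * SE`, with the standard error
#' from the fit covariance. Matches the nonlinear-regression intervals of
#' the standard statistical packages (t rather than normal quantiles, on
#' the residual degrees of freedom).
#'
#' @param fit A `hormesis_fit`.
#' @param parameter Name of a free parameter.
#' @param level Coverage probability, default 0.95.
#' @return A one-row tibble: `term`, `estimate`, `se`, `lower`, `upper`,
#'   `df`, `level`.
#' @export
wald_ci <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "hormesis_fit"))
  hf_assert_number(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  if (parameter %in% names(fit$fixed)) {
    hf_abort(sprintf("Parameter '%s' was fixed, not estimated.", parameter),
             "not_estimated")
  }
  if (!parameter %in% names(fit$estimates)) {
    hf_abort(sprintf("No free parameter '%s' in this fit.", parameter),
             "not_estimated")
  }
  if (is.null(fit$vcov)) {
    hf_abort("No covariance available (rank-deficient fit).", "not_estimated")
  }
  est <- unname(fit$estimates[parameter])
  se <- sqrt(fit$vcov[parameter, parameter])
  tq <- qt((1 + level) / 2, df = fit$df_res)
  tibble(term = parameter, estimate = est, se = se,
         lower = est - tq * se, upper = est + tq * se,
         df = fit$df_res, level = level)
}

#' Test the significance of hormesis
#'
#' Hormesis is declared significant at level `1 - level` when the two-sided
#' `level` confidence interval for the hormesis parameter `f` does not cover
#' zero and the estimate is positive. Works identically on natural fits and
#' on ED_K/LDS-reparameterized fits (where `f` remains free); an
#' M-parameterized fit has `f` eliminated and is not testable.
#'
#' @param fit A `hormesis_fit` with free `f`.
#' @param level Confidence level, default 0.95.
#' @return A `hormesis_test` list: `f_estimate`, `ci` (tibble from
#'   [wald_ci()]), `significant`, `excludes_zero` (two-sided exclusion
#'   regardless of sign), `alpha`.
#' @export
hormesis_test <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "hormesis_fit"))
  if (fit$family == "loglogistic4") {
    hf_abort("The log-logistic family has no hormesis parameter.",
             "not_testable")
  }
  if (!"f" %in% names(fit$estimates)) {
    hf_abort("f is not a free parameter of this fit (M parameterization).",
             "not_testable")
  }
  ci <- wald_ci(fit, "f", level = level)
  excludes <- ci$lower > 0 || ci$upper < 0
  structure(list(
    f_estimate = ci$estimate,
    ci = ci,
    significant = isTRUE(ci$estimate > 0 && ci$lower > 0),
    excludes_zero = excludes,
    alpha = 1 - level), class = "hormesis_test")
}

#' @export
print.hormesis_test <- function(x, ...) {
  cat(sprintf(
    "Hormesis test (CI%.0f for f vs 0): f = %.4g [%.4g, %.4g] -> %s\n",
    100 * (1 - x$alpha), x$f_estimate, x$ci$lower, x$ci$upper,
    if (x$significant) "significant hormesis" else "not significant"))
  invisible(x)
}

#' @method tidy hormesis_test
#' @export
tidy.hormesis_test <- function(x, ...) {
  dplyr::mutate(x$ci, significant = x$significant,
                excludes_zero = x$excludes_zero)
}

# delta-method SE of a scalar function of the free parameters
hf_delta_se <- function(fit, g) {
  if (is.null(fit$vcov)) {
    hf_abort("No covariance available for the delta method.", "not_estimated")
  }
  gr <- hf_grad(g, fit$estimates)
  v <- drop(t(gr) %*% fit$vcov %*% gr)
  if (!is.finite(v) || v < 0) {
    hf_abort("Non-finite delta-method variance.", "numeric_error")
  }
  sqrt(v)
}

#' Predict the mean response with a delta-method interval
#'
#' Evaluates the fitted mean function at the given doses and propagates the
#' parameter covariance to the prediction by the delta method
#' (SE^2 = g' Sigma g with g the gradient of the mean in the free
#' parameters). This is the route used for y_max, the response at the dose
#' of maximal stimulation.
#'
#' @param fit A `hormesis_fit`.
#' @param dose Numeric vector of non-negative doses.
#' @param level Confidence level for the t interval.
#' @return Tibble: `dose`, `estimate`, `se`, `lower`, `upper`.
#' @export
predict_response <- function(fit, dose, level = 0.95) {
  stopifnot(inherits(fit, "hormesis_fit"))
  spec <- fit$model
  tq <- qt((1 + level) / 2, df = fit$df_res)
  out <- purrr::map_dfr(dose, function(x0) {
    g <- function(par) spec$mean_fn(c(par, fit$fixed), x0)
    est <- g(fit$estimates)
    se <- hf_delta_se(fit, g)
    tibble(dose = x0, estimate = est, se = se,
           lower = est - tq * se, upper = est + tq * se)
  })
  out
}

#' @export
predict.hormesis_fit <- function(object, newdata = NULL, level = 0.95,
                                 se.fit = FALSE, ...) {
  dose <- if (is.null(newdata)) object$data$dose else {
    if (is.data.frame(newdata)) newdata$dose else as.numeric(newdata)
  }
  if (!se.fit) {
    return(object$model$mean_fn(c(object$estimates, object$fixed), dose))
  }
  predict_response(object, dose, level = level)
}

#' Maximal hormetic response y_max with confidence interval
#'
#' Locates the dose of maximal stimulation on the fitted curve and returns
#' the response there, absolutely and relative to the fitted control mean d
#' (in percent), each with a delta-method t interval. Because the mean
#' curve is stationary at M, the gradient of y_max in the parameters equals
#' the partial gradient at fixed dose, so the same code path as
#' [predict_response()] applies exactly.
#'
#' @param fit A hormetic `hormesis_fit` (f > 0).
#' @param level Confidence level.
#' @return Tibble with rows `y_max` (response units) and `y_max_rel`
#'   (percent of d): `quantity`, `estimate`, `se`, `lower`, `upper`.
#' @export
y_max_estimate <- function(fit, level = 0.95) {
  np <- hm_natural_params(fit)
  fun <- effective_doses_numeric(fit$family, np, K = numeric(0))
  m <- fun$value[fun$quantity == "M"]
  abs_row <- predict_response(fit, m, level = level)
  spec <- fit$model
  g_rel <- function(par) {
    full <- c(par, fit$fixed)
    p <- as.list(full)
    dd <- if ("d" %in% names(full)) full[["d"]] else {
      # reparameterized ED/LDS fit: d is implied
      p$ED_K <- full[[tail(spec$par_names, 1)]]
      solve_d_for_edk(spec$family, p, spec$target)
    }
    100 * spec$mean_fn(full, m) / dd
  }
  est_rel <- g_rel(fit$estimates)
  se_rel <- hf_delta_se(fit, g_rel)
  tq <- qt((1 + level) / 2, df = fit$df_res)
  tibble(quantity = c("y_max", "y_max_rel"),
         dose = m,
         estimate = c(abs_row$estimate, est_rel),
         se = c(abs_row$se, se_rel),
         lower = c(abs_row$lower, est_rel - tq * se_rel),
         upper = c(abs_row$upper, est_rel + tq * se_rel))
}

#' Quantify a pre-hormetic drop of a CRS curve
#'
#' Some CRS fits dip below the control mean before the hormetic rise. This
#' quantifies the drop by the dose of maximal drop `M_min`, the response
#' there `y_min` (absolute and in percent of d), and the dose `LDS_min`
#' where the drop disappears and the stimulation begins. Confidence
#' intervals for `M_min` and `LDS_min` exploit the multi-root structure of
#' the reparameterized models: the M- and LDS-parameterized models are
#' refitted with starting values at the pre-hormetic solutions (both roots
#' lie on the same fitted curve, so the refit sits at the same optimum);
#' when such a refit escapes to the main root the delta method on the
#' natural fit is used instead (`source` records which). The drop is flagged
#' significant when the interval for `100 y_min / d` excludes 100.
#'
#' @param fit A natural-parameter CRS `hormesis_fit` with f > 0.
#' @param level Confidence level.
#' @param min_depth Minimum relative depth `(d - y_min)/d` for a dip to
#'   count as a drop (default 1e-4). The CRS mean function always dips
#'   below d infinitesimally near dose zero — the stimulation kernel is
#'   exponentially flat there while the logistic decay is polynomial — so a
#'   threshold separates a structural drop from that negligible artifact.
#' @return A `pre_hormetic` list: `drop` (logical), `table` (tibble over
#'   `M_min`, `y_min`, `y_min_rel`, `LDS_min` with estimate/se/lower/upper/
#'   source), `significant_drop`, `fold_m` (M/M_min), `fold_lds`
#'   (LDS/LDS_min). When the curve never dips, `drop = FALSE` and the table
#'   is empty.
#' @export
pre_hormetic <- function(fit, level = 0.95, min_depth = 1e-4) {
  stopifnot(inherits(fit, "hormesis_fit"))
  if (fit$family != "cedergreen" || fit$model$kind != "natural") {
    hf_abort("Pre-hormetic quantification needs a natural CRS fit.",
             "value_error")
  }
  np <- hm_natural_params(fit)
  p <- as.list(np)
  if (p$f <= 0) hf_abort("f <= 0: no hormetic structure.", "no_hormesis")
  fun <- effective_doses_numeric(fit$family, np, K = numeric(0))
  m_main <- fun$value[fun$quantity == "M"]
  lds_main <- fun$value[fun$quantity == "LDS"]

  # search for a dip below d on (0, M)
  grid <- exp(seq(log(m_main * 1e-7), log(m_main * 0.999), length.out = 300))
  vals <- hm_mean(fit$family, np, grid)
  i <- which.min(vals)
  no_drop <- list(drop = FALSE, table = tibble(), significant_drop = FALSE,
                  fold_m = NA_real_, fold_lds = NA_real_,
                  M = m_main, LDS = lds_main)
  class(no_drop) <- "pre_hormetic"
  if (min(vals) >= p$d * (1 - min_depth)) return(no_drop)

  opt <- stats::optimize(function(x) hm_mean(fit$family, np, x),
                         lower = grid[max(i - 1, 1)],
                         upper = grid[min(i + 1, length(grid))],
                         tol = 1e-12)
  m_min <- opt$minimum
  y_min <- opt$objective
  if (y_min >= p$d * (1 - min_depth)) return(no_drop)
  lds_min <- hf_expanding_root(
    function(x) hm_mean(fit$family, np, x) - p$d,
    lo = m_min, hi_start = m_main, hi_limit = m_main, what = "LDS_min")

  tq <- qt((1 + level) / 2, df = fit$df_res)

  # CI via multi-root refit, falling back to the delta method
  ci_from_refit <- function(kind, start_dose, accept_below) {
    tg <- target_quantity(kind)
    spec <- build_reparam_model(fit$family, tg)
    tname <- tail(spec$par_names, 1)
    start <- c(np[setdiff(spec$par_names, tname)],
               setNames(start_dose, tname))
    a_arg <- if ("a" %in% names(fit$fixed)) unname(fit$fixed["a"]) else "free"
    refit <- try(suppressWarnings(
      fit_hormesis(fit$data, spec, start = start, a = a_arg,
                   control = hm_control(ladder = FALSE))), silent = TRUE)
    if (!inherits(refit, "try-error") &&
        is.finite(refit$estimates[tname]) &&
        refit$estimates[tname] < accept_below && !is.null(refit$vcov)) {
      ci <- wald_ci(refit, tname, level = level)
      return(tibble(estimate = ci$estimate, se = ci$se, lower = ci$lower,
                    upper = ci$upper, source = "multi_root_refit"))
    }
    # delta method on the natural fit: finite-difference gradient of the
    # implicitly defined dose in the free parameters
    g <- function(par) {
      full <- c(par, fit$fixed)
      if (kind == "M") {
        stats::optimize(function(x) hm_mean(fit$family, full, x),
                        lower = m_min / 10, upper = lds_min,
                        tol = 1e-12)$minimum
      } else {
        stats::uniroot(function(x) hm_mean(fit$family, full, x) - full[["d"]],
                       lower = m_min, upper = m_main, tol = 1e-12,
                       extendInt = "no")$root
      }
    }
    est <- start_dose
    se <- try(hf_delta_se(fit, g), silent = TRUE)
    if (inherits(se, "try-error")) se <- NA_real_
    tibble(estimate = est, se = se, lower = est - tq * se,
           upper = est + tq * se, source = "delta_from_natural")
  }

  row_mmin <- ci_from_refit("M", m_min, accept_below = lds_min)
  row_ldsmin <- ci_from_refit("LDS", lds_min, accept_below = m_main)

  # y_min: delta method at fixed dose (envelope: curve stationary at m_min)
  abs_row <- predict_response(fit, m_min, level = level)
  g_rel <- function(par) {
    full <- c(par, fit$fixed)
    100 * hm_mean(fit$family, full, m_min) / full[["d"]]
  }
  est_rel <- g_rel(fit$estimates)
  se_rel <- hf_delta_se(fit, g_rel)
  rel <- c(lower = est_rel - tq * se_rel, upper = est_rel + tq * se_rel)

  tab <- dplyr::bind_rows(
    dplyr::mutate(row_mmin, quantity = "M_min", .before = 1),
    tibble(quantity = "y_min", estimate = abs_row$estimate, se = abs_row$se,
           lower = abs_row$lower, upper = abs_row$upper,
           source = "delta_from_natural"),
    tibble(quantity = "y_min_rel", estimate = est_rel, se = se_rel,
           lower = rel[["lower"]], upper = rel[["upper"]],
           source = "delta_from_natural"),
    dplyr::mutate(row_ldsmin, quantity = "LDS_min", .before = 1))

  out <- list(drop = TRUE, table = tab,
              significant_drop = isTRUE(rel[["upper"]] < 100 ||
                                          rel[["lower"]] > 100),
              fold_m = m_main / m_min, fold_lds = lds_main / lds_min,
              M = m_main, LDS = lds_main)
  class(out) <- "pre_hormetic"
  out
}

#' @export
print.pre_hormetic <- function(x, ...) {
  if (!x$drop) {
    cat("No pre-hormetic drop: the fitted curve does not dip below d.\n")
    return(invisible(x))
  }
  cat("Pre-hormetic drop (exploratory):\n")
  print(x$table, n = Inf)
  cat(sprintf("  significant drop (CI of y_min%% vs 100): %s\n",
              x$significant_drop))
  cat(sprintf("  fold distances: M_min -> M %.3g x, LDS_min -> LDS %.3g x\n",
              x$fold_m, x$fold_lds))
  invisible(x)
}
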