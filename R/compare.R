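# Goodness-of-fit diagnostics and the two-model comparison: lack-of-fit F
# test against pure error, Pseudo-R^2, SS_res/df_res, a CI-overlap screen,
# relative bias of effective doses, and the four-case classification.

#' Lack-of-fit F test against pure error
#'
#' Decomposes the weighted residual sum of squares about the fitted curve
#' into pure error (replicate scatter about per-dose means) and lack of fit
#' (per-dose means about the curve): `SS_res = SS_lof + SS_pure`. The test
#' statistic is `F = (SS_lof/df_lof) / (SS_pure/df_pure)` with
#' `df_pure = n - #doses` and `df_lof = #doses - #free parameters`.
#'
#' @param fit A `hormesis_fit` on replicated data.
#' @return Tibble: `F`, `p`, `df_lof`, `df_pure`, `ss_lof`, `ss_pure`,
#'   `ss_res`.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "hormesis_fit"))
  d <- fit$data
  summ <- dose_summaries(d)
  if (all(summ$n < 2)) {
    hf_abort("Lack-of-fit needs replicated doses (pure-error df >= 1).",
             "not_testable")
  }
  ybar <- summ$mean[match(d$dose, summ$dose)]
  ss_pure <- sum(d$weight * (d$response - ybar)^2)
  ss_lof <- fit$ss_res - ss_pure
  df_pure <- nrow(d) - nrow(summ)
  df_lof <- fit$df_res - df_pure
  if (df_pure < 1 || df_lof < 1) {
    hf_abort("Insufficient degrees of freedom for the lack-of-fit test.",
             "not_testable")
  }
  Fstat <- (ss_lof / df_lof) / (ss_pure / df_pure)
  Fstat <- max(Fstat, 0)
  tibble(F = Fstat, p = pf(Fstat, df_lof, df_pure, lower.tail = FALSE),
         df_lof = df_lof, df_pure = df_pure,
         ss_lof = ss_lof, ss_pure = ss_pure, ss_res = fit$ss_res)
}

#' Pseudo-R2 of a nonlinear fit
#'
#' `1 - SS_res/SS_corrected` with weighted sums, the corrected total taken
#' about the weighted mean response. A descriptive quality index for
#' nonlinear models, to be read with caution — it can flatter a visibly
#' poor hormetic fit.
#'
#' @param fit A `hormesis_fit`, or a numeric `ss_res` with `ss_corrected`
#'   supplied.
#' @param ss_corrected Corrected total SS when `fit` is numeric.
#' @return The pseudo-R2 value.
#' @export
pseudo_r2 <- function(fit, ss_corrected = NULL) {
  if (inherits(fit, "hormesis_fit")) {
    ss_res <- fit$ss_res
    ss_corrected <- fit$ss_corrected
  } else {
    ss_res <- fit
  }
  if (is.null(ss_corrected) || !is.finite(ss_corrected) ||
      ss_corrected <= 0) {
    hf_abort("Pseudo-R2 undefined: corrected total SS must be positive.",
             "undefined_error")
  }
  1 - ss_res / ss_corrected
}

#' Relative bias between two model estimates
#'
#' `100 * (estimate_other - estimate_better) / estimate_better`, signed,
#' where `estimate_better` comes from the model judged to fit better. The
#' absolute value is usually reported alongside.
#'
#' @param estimate_better Estimate from the better-fitting model (non-zero).
#' @param estimate_other Estimate from the other model.
#' @return Signed percent bias (scalar or vector).
#' @export
relative_bias <- function(estimate_better, estimate_other) {
  if (any(estimate_better == 0)) {
    hf_abort("Relative bias undefined for a zero baseline estimate.",
             "undefined_error")
  }
  100 * (estimate_other - estimate_better) / estimate_better
}

# runs test on the signs of residuals ordered by dose: a surrogate for the
# visual observed-vs-fitted agreement judgment. Small p = systematic
# residual pattern.
hf_runs_test <- function(residuals, order) {
  r <- residuals[order]
  s <- sign(r)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(list(runs = 1, p = 1))
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(list(runs = runs, p = 1))
  z <- (runs - mu) / sqrt(v)
  list(runs = runs, p = 2 * pnorm(-abs(z)))
}

#' Classify a two-model comparison into the four cases
#'
#' Operationalizes the model-selection logic over the Brain-Cousens and CRS
#' fits: **case 1** — neither model shows significant hormesis (the
#' residual-pattern screen outcome is recorded in the rationale); **case
#' 2** — only BC shows significant hormesis, or both do and BC is clearly
#' the better fit; **case 3** — the CRS mirror image; **case 4** — both
#' significant with diagnostics differing by less than the margins
#' (`|delta pseudo-R2| < margins$pseudo_r2` and the SS_res/df ratio inside
#' `margins$ss_ratio`).
#'
#' @param bc_significant,crs_significant Hormesis-test outcomes.
#' @param bc_ss_df,crs_ss_df SS_res/df_res per model.
#' @param bc_pseudo_r2,crs_pseudo_r2 Pseudo-R2 per model.
#' @param bc_screen_p,crs_screen_p Runs-test p-values on dose-ordered
#'   residuals (NA skips the screen commentary).
#' @param margins List with `pseudo_r2` (default 0.01) and `ss_ratio`
#'   (default `c(0.9, 1.1)`).
#' @return List with `case` (one of `"case1_neither"`, `"case2_bc_better"`,
#'   `"case3_crs_better"`, `"case4_equal"`) and `rationale` (character
#'   vector of triggered rules).
#' @export
classify_case <- function(bc_significant, crs_significant,
                          bc_ss_df, crs_ss_df,
                          bc_pseudo_r2, crs_pseudo_r2,
                          bc_screen_p = NA, crs_screen_p = NA,
                          margins = list(pseudo_r2 = 0.01,
                                         ss_ratio = c(0.9, 1.1))) {
  rationale <- character(0)
  note <- function(...) rationale <<- c(rationale, sprintf(...))
  screen_fail <- function(p) is.finite(p) && p < 0.05

  if (!bc_significant && !crs_significant) {
    note("Neither model yields significant hormesis (CI95 of f covers 0).")
    if (screen_fail(bc_screen_p) && screen_fail(crs_screen_p)) {
      note("Both residual-pattern screens fail (runs test p < 0.05).")
    } else {
      note("Residual screen: BC p = %.3g, CRS p = %.3g (recorded only).",
           bc_screen_p, crs_screen_p)
    }
    return(list(case = "case1_neither", rationale = rationale))
  }
  if (bc_significant && !crs_significant) {
    note("Only the Brain-Cousens fit shows significant hormesis.")
    if (crs_ss_df < bc_ss_df) {
      note(paste0("CRS has the lower SS_res/df (%.4g vs %.4g) yet f is not ",
                  "significant: significance-driven choice."),
           crs_ss_df, bc_ss_df)
    }
    return(list(case = "case2_bc_better", rationale = rationale))
  }
  if (!bc_significant && crs_significant) {
    note("Only the CRS fit shows significant hormesis.")
    return(list(case = "case3_crs_better", rationale = rationale))
  }
  note("Both models yield significant hormesis.")
  dpr <- abs(bc_pseudo_r2 - crs_pseudo_r2)
  ratio <- bc_ss_df / crs_ss_df
  if (dpr < margins$pseudo_r2 && ratio >= margins$ss_ratio[1] &&
      ratio <= margins$ss_ratio[2]) {
    note("Diagnostics within margins (|dPseudo-R2| = %.4g, SS/df ratio %.3g).",
         dpr, ratio)
    return(list(case = "case4_equal", rationale = rationale))
  }
  if (bc_ss_df <= crs_ss_df) {
    note("BC has the lower SS_res/df (%.4g vs %.4g).", bc_ss_df, crs_ss_df)
    list(case = "case2_bc_better", rationale = rationale)
  } else {
    note("CRS has the lower SS_res/df (%.4g vs %.4g).", crs_ss_df, bc_ss_df)
    list(case = "case3_crs_better", rationale = rationale)
  }
}

#' Compare the Brain-Cousens and CRS fits of one data set
#'
#' Fits both hormetic families to the same weighted data, tests hormesis in
#' each, assembles goodness-of-fit diagnostics (lack-of-fit F, pseudo-R2,
#' SS_res/df) and effective-dose tables, screens CI overlap between the two
#' models' estimates, computes the relative bias of each quantity against
#' the better-fitting model, and classifies the comparison into one of the
#' four cases (see [classify_case()]).
#'
#' @param data A weighted `dose_response` tibble.
#' @param K ED_K level(s) for the effective-dose table, default 50.
#' @param convention See [target_quantity()].
#' @param level Confidence level.
#' @param a CRS shape-exponent handling, see [fit_hormesis()].
#' @param margins Case-4 margins, see [classify_case()].
#' @return A `hormesis_comparison` object: `fits` (named list), `tests`,
#'   `diagnostics` tibble, `ed` (both models' effective-dose tables),
#'   `bias` tibble (per quantity: both estimates, signed and absolute
#'   relative bias, CI-overlap flag), `case`, `rationale`. The CI-overlap
#'   column is an indication only, not a test.
#' @export
compare_hormesis_models <- function(data, K = 50,
                                    convention = c("relative_to_control",
                                                   "relative_to_range"),
                                    level = 0.95, a = "auto",
                                    margins = list(pseudo_r2 = 0.01,
                                                   ss_ratio = c(0.9, 1.1))) {
  convention <- match.arg(convention)
  fit_one <- function(family) {
    try(suppressWarnings(fit_hormesis(data, family, a = a)), silent = TRUE)
  }
  fits <- list(brain_cousens = fit_one("brain_cousens"),
               cedergreen = fit_one("cedergreen"))
  failed <- vapply(fits, inherits, logical(1), "try-error")
  if (all(failed)) {
    hf_abort("Both model fits failed.", "non_convergence")
  }
  if (any(failed)) {
    rlang::warn(sprintf("%s fit failed; partial report.",
                        names(fits)[failed]))
  }

  diag_of <- function(fit) {
    if (inherits(fit, "try-error")) {
      return(tibble(ss_res_over_df = NA_real_, pseudo_r2 = NA_real_,
                    lof_F = NA_real_, lof_p = NA_real_,
                    screen_p = NA_real_))
    }
    lof <- tryCatch(lack_of_fit(fit), error = function(e)
      tibble(F = NA_real_, p = NA_real_))
    ord <- order(fit$data$dose)
    screen <- hf_runs_test(fit$residuals, ord)
    tibble(ss_res_over_df = fit$ss_res / fit$df_res,
           pseudo_r2 = pseudo_r2(fit),
           lof_F = lof$F, lof_p = lof$p, screen_p = screen$p)
  }
  diagnostics <- dplyr::bind_rows(
    dplyr::mutate(diag_of(fits$brain_cousens), model = "brain_cousens",
                  .before = 1),
    dplyr::mutate(diag_of(fits$cedergreen), model = "cedergreen",
                  .before = 1))

  test_of <- function(fit) {
    if (inherits(fit, "try-error")) return(NULL)
    tryCatch(hormesis_test(fit, level = level), error = function(e) NULL)
  }
  tests <- list(brain_cousens = test_of(fits$brain_cousens),
                cedergreen = test_of(fits$cedergreen))
  sig <- vapply(tests, function(t) isTRUE(t$significant), logical(1))

  ed_of <- function(fit) {
    if (inherits(fit, "try-error")) return(NULL)
    tryCatch(effective_doses(fit, K = K, convention = convention,
                             level = level),
             error = function(e) NULL)
  }
  ed <- list(brain_cousens = ed_of(fits$brain_cousens),
             cedergreen = ed_of(fits$cedergreen))

  if (any(failed)) {
    surviving <- names(fits)[!failed]
    case <- list(case = sprintf("forced_%s", surviving),
                 rationale = sprintf(
                   "Only the %s fit succeeded; comparison not possible.",
                   surviving))
    bias <- tibble()
  } else {
    cls <- classify_case(
      bc_significant = sig[["brain_cousens"]],
      crs_significant = sig[["cedergreen"]],
      bc_ss_df = diagnostics$ss_res_over_df[1],
      crs_ss_df = diagnostics$ss_res_over_df[2],
      bc_pseudo_r2 = diagnostics$pseudo_r2[1],
      crs_pseudo_r2 = diagnostics$pseudo_r2[2],
      bc_screen_p = diagnostics$screen_p[1],
      crs_screen_p = diagnostics$screen_p[2],
      margins = margins)
    case <- cls

    # better model for bias baselining: hormesis significance first (one
    # significant model wins), otherwise lower SS_res/df
    better <- if (sig[["brain_cousens"]] != sig[["cedergreen"]]) {
      names(sig)[sig]
    } else if (diagnostics$ss_res_over_df[1] <=
               diagnostics$ss_res_over_df[2]) {
      "brain_cousens"
    } else "cedergreen"
    other <- setdiff(c("brain_cousens", "cedergreen"), better)

    bias <- if (!is.null(ed[[better]]) && !is.null(ed[[other]])) {
      key <- function(t) paste(t$quantity, t$K)
      common <- intersect(key(ed[[better]]), key(ed[[other]]))
      b1 <- ed[[better]][match(common, key(ed[[better]])), ]
      b2 <- ed[[other]][match(common, key(ed[[other]])), ]
      tibble(quantity = b1$quantity, K = b1$K,
             better_model = better,
             estimate_better = b1$estimate, estimate_other = b2$estimate,
             bias_pct = relative_bias(b1$estimate, b2$estimate),
             abs_bias_pct = abs(relative_bias(b1$estimate, b2$estimate)),
             ci_overlap = (b2$estimate >= b1$lower &
                             b2$estimate <= b1$upper) |
               (b1$estimate >= b2$lower & b1$estimate <= b2$upper))
    } else tibble()
  }

  structure(list(fits = fits, tests = tests, diagnostics = diagnostics,
                 ed = ed, bias = bias, case = case$case,
                 rationale = case$rationale, margins = margins,
                 level = level),
            class = "hormesis_comparison")
}

#' @export
print.hormesis_comparison <- function(x, ...) {
  cat("Hormetic model comparison (Brain-Cousens vs Cedergreen)\n")
  cat(sprintf("  case: %s\n", x$case))
  for (r in x$rationale) cat(sprintf("   - %s\n", r))
  cat("  diagnostics:\n")
  print(x$diagnostics)
  if (nrow(x$bias) > 0) {
    cat("  relative bias of effective doses (CI overlap is indicative only):\n")
    print(x$bias, n = Inf)
  }
  invisible(x)
}

#' @method tidy hormesis_comparison
#' @export
tidy.hormesis_comparison <- function(x, ...) x$bias

#' @method glance hormesis_comparison
#' @export
glance.hormesis_comparison <- function(x, ...) {
  tibble(case = x$case,
         bc_pseudo_r2 = x$diagnostics$pseudo_r2[1],
         crs_pseudo_r2 = x$diagnostics$pseudo_r2[2],
         bc_ss_res_over_df = x$diagnostics$ss_res_over_df[1],
         crs_ss_res_over_df = x$diagnostics$ss_res_over_df[2],
         bc_significant = isTRUE(x$tests$brain_cousens$significant),
         crs_significant = isTRUE(x$tests$cedergreen$significant))
}

#' Write a comparison report
#'
#' Writes the per-quantity bias table as CSV and the full report (case,
#' rationale, diagnostics, tests) as JSON.
#'
#' @param comparison A `hormesis_comparison`.
#' @param csv_path,json_path Output paths (NULL skips).
#' @return The comparison, invisibly.
#' @export
write_comparison <- function(comparison, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(comparison$bias, csv_path)
  if (!is.null(json_path)) {
    x <- list(case = comparison$case, rationale = comparison$rationale,
              diagnostics = comparison$diagnostics,
              bias = comparison$bias)
    jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(comparison)
}
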