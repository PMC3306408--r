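# Weighted nonlinear least-squares fitting for the hormetic families and
# their reparameterizations. The optimizer is Levenberg-Marquardt
# (minpack.lm::nls.lm) on sqrt(w)-scaled residuals with box constraints
# (c >= 0, e > 0, a > 0, target doses > 0), so the minimized objective is
# the weighted residual sum of squares sum(w * (y - mu(x))^2).

#' Fitting control parameters
#'
#' @param ftol,ptol Relative convergence tolerances on the sum of squares
#'   and on the parameters passed to the Levenberg-Marquardt iteration.
#' @param maxiter Maximum number of iterations.
#' @param ladder Retry failed fits along the starting-value preset ladder.
#' @return A list of control settings.
#' @export
hm_control <- function(ftol = 1e-10, ptol = 1e-10, maxiter = 1000,
                       ladder = TRUE) {
  list(ftol = ftol, ptol = ptol, maxiter = maxiter, ladder = isTRUE(ladder))
}

# ---- model specification ---------------------------------------------------

# normalize a model argument (family name or reparam_spec) into an internal
# spec: list(kind, family, target, par_names, mean_fn(params, dose))
hf_as_spec <- function(model) {
  if (inherits(model, "reparam_spec")) {
    return(list(kind = "reparam", family = model$family,
                target = model$target, par_names = model$par_names,
                mean_fn = model$mean_fn, reparam = model))
  }
  family <- hf_match_family(model)
  list(kind = "natural", family = family, target = NULL,
       par_names = hf_param_names(family),
       mean_fn = function(params, dose) hm_mean(family, params, dose),
       reparam = NULL)
}

hf_default_bounds <- function(par_names) {
  lower <- setNames(rep(-Inf, length(par_names)), par_names)
  upper <- setNames(rep(Inf, length(par_names)), par_names)
  for (nm in intersect(c("e", "a", "ED_K", "LDS", "M"), par_names)) {
    lower[nm] <- 1e-10
  }
  if ("c" %in% par_names) lower["c"] <- 0
  list(lower = lower, upper = upper)
}

# ---- starting values -------------------------------------------------------

#' Starting values deduced from the data
#'
#' Reproduces the graphical starting-value protocol: `d` starts at the
#' untreated-control mean; `c` at 0; `e` at 0.8 times the dose whose mean
#' response is nearest 50% of the control mean (slightly below the
#' anticipated ED_50); `b` at 2; `a` at 1; and `f` at 0 when the dose means
#' never rise above the control, otherwise at a value matched to the
#' observed maximum stimulation. The attached ladder enumerates the preset
#' menus retried on failure — `f` in \{0, 1, 10, 100\} (scaled to the
#' response/dose units of the data), `a` in \{0.1, 0.5, 1\}, `b` in
#' \{1, 2, 3\} — with `f` varied outermost, then `a`, then `b`.
#'
#' @param data A `dose_response` tibble (untreated control required).
#' @param model A family name or a [build_reparam_model()] spec.
#' @return A list with `start` (named vector over the model's free
#'   parameters) and `ladder` (a list of alternative start vectors).
#' @export
initial_values <- function(data, model = "cedergreen") {
  spec <- hf_as_spec(model)
  summ <- dose_summaries(data)
  if (!any(summ$dose == 0)) {
    hf_abort("Starting values need an untreated control (dose 0).",
             "start_value_error")
  }
  d0 <- summ$mean[summ$dose == 0]
  nz <- summ[summ$dose > 0, ]
  stim <- max(nz$mean) - d0
  x_at_max <- nz$dose[which.max(nz$mean)]
  e0 <- 0.8 * nz$dose[which.min(abs(nz$mean - 0.5 * d0))]
  if (e0 <= 0) e0 <- median(nz$dose)
  b0 <- 2
  a0 <- 1

  f0 <- 0
  if (stim > 0) {
    f0 <- if (spec$family == "brain_cousens") {
      stim / max(x_at_max, 1e-12)
    } else {
      stim / max(hf_crs_kernel(x_at_max, a0), 0.05)
    }
  }

  base <- c(b = b0, c = 0, d = d0, e = e0, f = f0, a = a0)

  # seed target dosages from the numeric oracle applied to a pilot natural fit
  if (spec$kind == "reparam") {
    tname <- tail(spec$par_names, 1)
    pilot <- try(suppressWarnings(
      fit_hormesis(data, spec$family,
                   a = if (spec$family == "cedergreen") a0 else NULL,
                   control = hm_control(ladder = TRUE))), silent = TRUE)
    tval <- NA_real_
    if (!inherits(pilot, "try-error")) {
      fun <- try(suppressWarnings(effective_doses_numeric(
        spec$family, hm_natural_params(pilot),
        K = if (spec$target$kind == "ED_K") spec$target$K else 50,
        convention = spec$target$convention)), silent = TRUE)
      if (!inherits(fun, "try-error")) {
        tval <- switch(spec$target$kind,
          ED_K = fun$value[fun$quantity == "ED_K"][1],
          LDS = fun$value[fun$quantity == "LDS"][1],
          M = fun$value[fun$quantity == "M"][1])
      }
    }
    if (!is.finite(tval) || tval <= 0) {
      tval <- switch(spec$target$kind, ED_K = e0, LDS = 0.5 * e0, M = 0.2 * e0)
    }
    base[tname] <- tval
  }

  start <- base[spec$par_names]

  # preset menus, f outermost, then a, then b
  f_scale <- d0 / 100
  if (spec$family == "brain_cousens") {
    f_scale <- f_scale / max(x_at_max, 1e-12)
  }
  f_menu <- if ("f" %in% spec$par_names) c(0, 1, 10, 100) * f_scale else NA
  a_menu <- if ("a" %in% spec$par_names) c(0.1, 0.5, 1) else NA
  b_menu <- c(1, 2, 3)
  ladder <- list()
  for (fv in f_menu) for (av in a_menu) for (bv in b_menu) {
    s <- start
    if (!is.na(fv)) s["f"] <- fv
    if (!is.na(av)) s["a"] <- av
    s["b"] <- bv
    ladder[[length(ladder) + 1]] <- s
  }
  list(start = start, ladder = ladder)
}

# ---- LM engine -------------------------------------------------------------

hf_fit_engine <- function(x, y, w, mean_fn, start, lower, upper, control,
                          fixed = NULL) {
  sw <- sqrt(w)
  resid_fn <- function(par) {
    mu <- tryCatch(mean_fn(c(par, fixed), x),
                   error = function(e) rep(NA_real_, length(x)))
    r <- sw * (y - mu)
    r[!is.finite(r)] <- 1e10
    r
  }
  # central-difference jacobian: markedly more accurate than the default
  # forward differences in the flat, strongly correlated valleys these
  # families produce, and decisive for full convergence there
  jac_fn <- function(par, ...) hf_jacobian(resid_fn, unlist(par))
  lm_once <- function(p0) {
    try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn, jac = jac_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        ftol = control$ftol, ptol = control$ptol,
        maxiter = min(control$maxiter, 1024))), silent = TRUE)
  }
  res <- lm_once(start)
  if (inherits(res, "try-error")) {
    return(list(ok = FALSE, message = as.character(res)))
  }
  n_iter <- res$niter
  # Polishing loop: these families produce long curved valleys of strongly
  # correlated parameters where damped least squares can stall short of
  # stationarity. A bounded quasi-Newton pass (nlminb/PORT) on the summed
  # objective, alternated with LM restarts, drives the fit to a genuine
  # KKT point; it terminates immediately when LM already converged fully.
  obj <- function(p) sum(resid_fn(p)^2)
  if (isTRUE(res$info %in% 1:4)) {
    for (r in 1:4) {
      ss_prev <- sum(res$fvec^2)
      p_cur <- unlist(res$par)
      qn <- try(stats::nlminb(p_cur, obj, lower = lower, upper = upper,
                              control = list(rel.tol = 1e-15,
                                             x.tol = 1e-12,
                                             iter.max = 500,
                                             eval.max = 2000)),
                silent = TRUE)
      p_next <- if (!inherits(qn, "try-error") && qn$objective < ss_prev) {
        pmin(pmax(qn$par, lower), upper)
      } else p_cur
      res2 <- lm_once(p_next)
      if (inherits(res2, "try-error")) break
      n_iter <- n_iter + res2$niter
      if (sum(res2$fvec^2) <= ss_prev) res <- res2
      if (ss_prev - sum(res$fvec^2) <= 1e-12 * max(ss_prev, 1e-300)) break
    }
  }
  par <- res$par
  ok <- res$info %in% 1:4 && all(is.finite(unlist(par)))
  ss_res <- sum(res$fvec^2)
  list(ok = ok, par = unlist(par), ss_res = ss_res, info = res$info,
       n_iter = n_iter, resid_fn = resid_fn,
       message = res$message)
}

# covariance s^2 (J'J)^-1 from the sqrt(w)-scaled residual jacobian
hf_fit_vcov <- function(resid_fn, par, ss_res, df_res) {
  J <- -hf_jacobian(resid_fn, par)
  JtJ <- crossprod(J)
  s2 <- ss_res / df_res
  V <- try(solve(JtJ) * s2, silent = TRUE)
  if (inherits(V, "try-error") || any(!is.finite(V)) ||
      any(diag(V) < 0)) {
    ev <- eigen(JtJ, symmetric = TRUE)
    worst <- ev$vectors[, which.min(abs(ev$values))]
    dir <- names(par)[which.max(abs(worst))]
    return(list(ok = FALSE, vcov = NULL, direction = dir))
  }
  dimnames(V) <- list(names(par), names(par))
  list(ok = TRUE, vcov = V, direction = NULL)
}

# ---- user-facing fit -------------------------------------------------------

#' Fit a hormetic dose-response model
#'
#' Fits a natural-parameter family (Brain-Cousens, Cedergreen/CRS, or the
#' monotone four-parameter log-logistic) or a reparameterized variant in
#' which an effective dose (ED_K, LDS or M) is a free parameter, by weighted
#' Levenberg-Marquardt least squares. Weights are taken from the data's
#' `weight` column (see [compute_weights()]); the objective is
#' \eqn{\sum_i w_i (y_i - \mu(x_i; \theta))^2}. Bounds `c >= 0`, `e > 0`,
#' `a > 0` are enforced throughout.
#'
#' If the first fit attempt fails, starting values are retried along the
#' preset ladder of [initial_values()] (`f` menu outermost, then `a`, then
#' `b`); the attempts are recorded in the returned `ladder_trace`.
#'
#' For the CRS family the shape exponent `a` can rarely be estimated freely
#' from typical designs. `a = "auto"` (default) first attempts free
#' estimation and falls back to profiling on failure; `a = "profile"` forces
#' the profile: the model is refitted with `a` fixed at each value of
#' `a_grid` and the fit with the smallest weighted residual sum of squares
#' is returned (`a` then counts as fixed, not estimated, in the degrees of
#' freedom). A numeric `a` fixes it at that value; `a = "free"` estimates it
#' with no fallback.
#'
#' @param data A `dose_response` tibble (use [compute_weights()] first for
#'   the inverse-SD weighting; unweighted fits use weight 1).
#' @param model A family name (see [hormesis_families()]) or a
#'   [build_reparam_model()] spec.
#' @param start Optional named starting values over the model's free
#'   parameters; defaults to [initial_values()].
#' @param a For CRS-family models: `"auto"`, `"free"`, `"profile"`, or a
#'   number to fix `a`. Ignored for other families.
#' @param a_grid Grid for the profile, default `seq(0.07, 1.75, by = 0.02)`.
#' @param lower,upper Optional named bound overrides.
#' @param control See [hm_control()].
#' @return An object of class `hormesis_fit` with components `estimates`,
#'   `vcov`, `ss_res`, `df_res`, `ss_corrected`, `converged`, `n_iter`,
#'   `fixed`, `implied` (the eliminated natural parameter, for
#'   reparameterized fits), `start_used`, `ladder_trace`, and the data.
#'   Supports [coef()], [vcov()], [predict()], [tidy()], [glance()] and
#'   [autoplot()].
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_dose_response()
#' d <- compute_weights(d)
#' fit <- fit_hormesis(d, "cedergreen", a = 1)
#' tidy(fit)
fit_hormesis <- function(data, model = "cedergreen", start = NULL,
                         a = "auto", a_grid = seq(0.07, 1.75, by = 0.02),
                         lower = NULL, upper = NULL,
                         control = hm_control()) {
  spec <- hf_as_spec(model)
  if (!"weight" %in% names(data)) data$weight <- 1
  if (any(data$weight <= 0) || any(!is.finite(data$weight))) {
    hf_abort("All weights must be positive and finite.", "value_error")
  }

  has_a <- "a" %in% spec$par_names
  a_mode <- "free"
  fixed <- NULL
  if (has_a && !is.null(a)) {
    if (is.numeric(a)) {
      hf_assert_number(a, "a", lower = 1e-12)
      fixed <- c(a = as.numeric(a))
      a_mode <- "fixed"
    } else {
      a_mode <- match.arg(a, c("auto", "free", "profile"))
    }
  }

  fit1 <- if (a_mode == "profile") NULL else {
    hf_fit_once(data, spec, start, fixed, lower, upper, control)
  }

  needs_profile <- a_mode == "profile" ||
    (a_mode == "auto" && has_a && is.null(fixed) && !hf_fit_usable(fit1))
  if (needs_profile) {
    fit1 <- hf_fit_profile_a(data, spec, start, a_grid, lower, upper, control)
  }
  if (is.null(fit1) || !fit1$ok) {
    hf_abort(paste0("Model fit failed after exhausting the starting-value ",
                    "ladder.", if (!is.null(fit1$direction)) sprintf(
                      " Least-identifiable direction: %s.", fit1$direction)),
             "non_convergence", trace = fit1$trace)
  }
  hf_finalize_fit(fit1, data, spec, control)
}

# is a fit attempt usable for the "auto" a-mode (converged, full rank,
# hormesis parameter estimable)?
hf_fit_usable <- function(fit) {
  if (is.null(fit) || !isTRUE(fit$ok)) return(FALSE)
  if (!isTRUE(fit$vcov_ok)) return(FALSE)
  if ("f" %in% names(fit$par)) {
    se_f <- sqrt(fit$vcov["f", "f"])
    if (!is.finite(se_f) || se_f <= 0) return(FALSE)
  }
  TRUE
}

# one fit (with ladder retries); returns internal result list
hf_fit_once <- function(data, spec, start, fixed, lower, upper, control) {
  free_names <- setdiff(spec$par_names, names(fixed))
  bounds <- hf_default_bounds(free_names)
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper

  user_start <- !is.null(start)
  if (user_start) {
    start <- start[free_names]
    if (anyNA(start)) {
      hf_abort("`start` must name every free parameter.", "value_error")
    }
    if (any(start < bounds$lower - 1e-12) || any(start > bounds$upper + 1e-12)) {
      hf_abort("Starting values violate the parameter bounds.", "value_error")
    }
    starts <- list(start)
  } else {
    iv <- initial_values(data, if (spec$kind == "reparam") spec$reparam else
      spec$family)
    starts <- c(list(iv$start), if (control$ladder) iv$ladder)
    starts <- lapply(starts, function(s) {
      s <- s[free_names]
      pmin(pmax(s, bounds$lower), bounds$upper)
    })
  }
  if (user_start && control$ladder) {
    iv <- try(initial_values(data, if (spec$kind == "reparam") spec$reparam
                             else spec$family), silent = TRUE)
    if (!inherits(iv, "try-error")) {
      starts <- c(starts, lapply(iv$ladder, function(s) {
        s <- s[free_names]
        pmin(pmax(s, bounds$lower), bounds$upper)
      }))
    }
  }

  n <- nrow(data)
  df_res <- n - length(free_names)
  if (df_res < 1) {
    hf_abort("Fewer observations than free parameters.", "value_error")
  }

  trace <- list()
  fallback <- NULL
  for (i in seq_along(starts)) {
    s <- starts[[i]]
    eng <- hf_fit_engine(data$dose, data$response, data$weight, spec$mean_fn,
                         s, bounds$lower, bounds$upper, control, fixed)
    # a properly estimated fit keeps the inhibitory branch decreasing
    # (b > 0); a sign-inverted logistic is a degenerate local optimum
    proper <- isTRUE(eng$ok) &&
      (!"b" %in% names(eng$par) || eng$par[["b"]] > 0)
    trace[[i]] <- tibble(attempt = i,
                         start = list(s),
                         converged = isTRUE(eng$ok),
                         proper = proper,
                         ss_res = if (isTRUE(eng$ok)) eng$ss_res else NA_real_)
    if (isTRUE(eng$ok)) {
      res <- list(ok = TRUE, par = eng$par, ss_res = eng$ss_res,
                  n_iter = eng$n_iter, info = eng$info,
                  resid_fn = eng$resid_fn,
                  df_res = df_res, fixed = fixed, start_used = s)
      if (proper) {
        vc <- hf_fit_vcov(eng$resid_fn, eng$par, eng$ss_res, df_res)
        res$vcov <- vc$vcov; res$vcov_ok <- vc$ok
        res$direction <- vc$direction
        res$trace <- dplyr::bind_rows(trace)
        return(res)
      }
      if (is.null(fallback) || eng$ss_res < fallback$ss_res) fallback <- res
    }
  }
  if (!is.null(fallback)) {
    rlang::warn("No start converged to a decreasing curve (b > 0); returning the best converged fit.")
    vc <- hf_fit_vcov(fallback$resid_fn, fallback$par, fallback$ss_res,
                      df_res)
    fallback$vcov <- vc$vcov; fallback$vcov_ok <- vc$ok
    fallback$direction <- vc$direction
    fallback$trace <- dplyr::bind_rows(trace)
    return(fallback)
  }
  list(ok = FALSE, trace = dplyr::bind_rows(trace), direction = NULL)
}

# profile fit over a fixed-a grid, smallest weighted SS wins
hf_fit_profile_a <- function(data, spec, start, a_grid, lower, upper,
                             control) {
  best <- NULL
  for (av in a_grid) {
    f <- try(hf_fit_once(data, spec, start, c(a = av), lower, upper, control),
             silent = TRUE)
    if (inherits(f, "try-error") || !isTRUE(f$ok)) next
    if (is.null(best) || f$ss_res < best$ss_res) best <- f
  }
  if (is.null(best)) {
    return(list(ok = FALSE, trace = NULL, direction = NULL))
  }
  best
}

hf_finalize_fit <- function(res, data, spec, control) {
  par <- res$par
  full <- c(par, res$fixed)
  implied <- NULL
  if (spec$kind == "reparam") {
    p <- as.list(full)
    if (spec$target$kind == "M") {
      implied <- c(f = solve_f_for_m_quiet(spec$family, p))
    } else {
      p$ED_K <- p[[tail(spec$par_names, 1)]]
      implied <- c(d = solve_d_for_edk(spec$family, p, spec$target))
    }
  }
  wbar <- weighted.mean(data$response, data$weight)
  ss_corr <- sum(data$weight * (data$response - wbar)^2)
  fitted <- spec$mean_fn(full, data$dose)

  np <- c(full, implied)
  if (spec$family == "brain_cousens" &&
      all(c("b", "f") %in% names(np)) &&
      is.finite(np["b"]) && np["b"] <= 1 && np["f"] > 0) {
    rlang::warn("Brain-Cousens fit has b <= 1 with f > 0; interpret with care.")
  }
  if (all(c("c", "d") %in% names(np)) && np["c"] > np["d"]) {
    rlang::warn("Fitted c exceeds d; the fit may not be interpretable.")
  }

  structure(list(
    model = spec, family = spec$family,
    estimates = par, fixed = res$fixed %||% setNames(numeric(0), character(0)),
    implied = implied,
    vcov = res$vcov, vcov_ok = res$vcov_ok,
    ss_res = res$ss_res, df_res = res$df_res, ss_corrected = ss_corr,
    converged = TRUE, n_iter = res$n_iter, info = res$info,
    start_used = res$start_used, ladder_trace = res$trace,
    data = data, fitted = fitted, residuals = data$response - fitted,
    weight_scheme = attr(data, "weight_scheme") %||% "none",
    control = control), class = "hormesis_fit")
}

#' Full natural parameters of a fitted model
#'
#' Assembles the complete natural parameter vector (b, c, d, e, f, a as
#' applicable) of a fit: free estimates, fixed values, and — for
#' reparameterized fits — the eliminated parameter implied by the target
#' dose.
#'
#' @param fit A `hormesis_fit`.
#' @return Named numeric vector of natural parameters.
#' @export
hm_natural_params <- function(fit) {
  stopifnot(inherits(fit, "hormesis_fit"))
  full <- c(fit$estimates, fit$fixed, fit$implied)
  full[hf_param_names(fit$family)]
}

#' @export
coef.hormesis_fit <- function(object, ...) object$estimates

#' @export
vcov.hormesis_fit <- function(object, ...) object$vcov

#' @export
nobs.hormesis_fit <- function(object, ...) nrow(object$data)

#' @export
df.residual.hormesis_fit <- function(object, ...) object$df_res

#' @export
fitted.hormesis_fit <- function(object, ...) object$fitted

#' @export
residuals.hormesis_fit <- function(object, ...) object$residuals

#' @export
print.hormesis_fit <- function(x, ...) {
  kind <- if (x$model$kind == "reparam") {
    sprintf("%s reparameterized for %s", x$family, x$model$target$kind)
  } else x$family
  cat(sprintf("Hormetic dose-response fit: %s\n", kind))
  cat(sprintf("  %d observations, weighted SS_res = %.6g on %d df\n",
              nrow(x$data), x$ss_res, x$df_res))
  print(tidy(x), n = Inf)
  if (length(x$fixed) > 0) {
    cat(sprintf("  fixed: %s\n",
                paste(sprintf("%s = %g", names(x$fixed), x$fixed),
                      collapse = ", ")))
  }
  if (!is.null(x$implied)) {
    cat(sprintf("  implied %s = %g\n", names(x$implied), x$implied))
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit A `hormesis_fit`.
#' @return JSON string with estimates, standard errors, fixed parameters,
#'   SS_res, df_res and convergence metadata.
#' @export
fit_to_json <- function(fit) {
  se <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov)) else NULL
  jsonlite::toJSON(list(
    family = fit$family,
    kind = fit$model$kind,
    estimates = as.list(fit$estimates),
    se = as.list(se),
    fixed = as.list(fit$fixed),
    implied = as.list(fit$implied),
    ss_res = fit$ss_res, df_res = fit$df_res,
    pseudo_r2 = 1 - fit$ss_res / fit$ss_corrected,
    converged = fit$converged, n_iter = fit$n_iter),
    auto_unbox = TRUE, digits = NA, na = "null")
}
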