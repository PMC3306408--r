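# Reparameterizations that make effective doses directly estimable.
#
# The defining relationships:
#   ED_K: the mean response at x = ED_K equals the target level
#         (1 - K/100)*d                ("relative_to_control", default)
#         c + (1 - K/100)*(d - c)      ("relative_to_range")
#     Both are linear in d; solving for d and substituting into the mean
#     function yields a model in which ED_K is a free parameter. LDS is the
#     special case K = 0 (the two conventions coincide there).
#   M: the dose-derivative of the mean function vanishes at x = M. The
#     stationarity equation is linear in f; solving for f and substituting
#     yields a model in which M is a free parameter.
#
# Closed forms, with L = (x0/e)^b, D = 1 + L evaluated at the target dose x0,
# p = 1 - K/100, and s(x0) = x0 for BC, s(x0) = exp(-x0^(-a)) for CRS:
#   relative_to_control: d = (c*(1 - D) - f*s(x0)) / (1 - p*D)
#   relative_to_range:   d = c - f*s(x0) / (1 - p*D)
#   M (BC):  f = (d - c) * bL/M / (D - bL)
#   M (CRS): f = (d - c) * bL/M / (s'(M)*D - s(M)*bL/M),  s'(M) = s(M)*a*M^(-a-1)
# Correctness is enforced by the curve-set-equivalence property: the
# reparameterized mean evaluated at any admissible parameters is identical
# to the natural-parameter mean with the implied d or f.

#' Describe a target effective dose
#'
#' @param kind One of `"ED_K"`, `"LDS"`, `"M"`. `ED_K` is the dose causing
#'   K% inhibition; `LDS` (limited dose for stimulation, where the hormetic
#'   stimulation disappears) is `ED_K` with K = 0; `M` is the dose of maximal
#'   stimulation (stationary point of the mean curve).
#' @param K Percent inhibition in (0, 100); required for `ED_K`, forced to 0
#'   for `LDS`, unused for `M`.
#' @param convention `"relative_to_control"` (target level `(1 - K/100) d`,
#'   the default) or `"relative_to_range"` (`c + (1 - K/100)(d - c)`). The
#'   two coincide when c = 0 (the usual constraint) and at K = 0.
#' @return A `target_quantity` list.
#' @export
target_quantity <- function(kind = c("ED_K", "LDS", "M"), K = NULL,
                            convention = c("relative_to_control",
                                           "relative_to_range")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  if (kind == "ED_K") {
    hf_assert_number(K, "K")
    if (K <= 0 || K >= 100) {
      hf_abort("K must lie strictly between 0 and 100.", "value_error")
    }
  } else if (kind == "LDS") {
    K <- 0
  } else {
    K <- NA_real_
  }
  structure(list(kind = kind, K = K, convention = convention),
            class = "target_quantity")
}

# target response level for an ED_K/LDS target, given c and d
hf_target_level <- function(target, c, d) {
  p <- 1 - target$K / 100
  if (target$convention == "relative_to_control") p * d else c + p * (d - c)
}

#' Solve the ED_K defining relationship for d
#'
#' Returns the control-mean parameter `d` implied by requiring the mean
#' response at `x = ED_K` to equal the K%-inhibition level. The relationship
#' is linear in `d`; the closed form is used.
#'
#' @inheritParams hm_mean
#' @param params Named parameters of the family **without** `d`, plus the
#'   target dose as `ED_K`.
#' @param target A [target_quantity()] of kind `ED_K` or `LDS`.
#' @return The implied `d` (scalar).
#' @export
solve_d_for_edk <- function(family, params, target) {
  family <- hf_match_family(family)
  if (!inherits(target, "target_quantity") || target$kind == "M") {
    hf_abort("`target` must be an ED_K or LDS target_quantity.", "value_error")
  }
  p <- as.list(params)
  x0 <- p$ED_K %||% p$LDS
  hf_assert_number(x0, "ED_K", lower = .Machine$double.xmin)
  pk <- 1 - target$K / 100
  L <- hf_logistic_term(x0, p$b, p$e)
  D <- 1 + L
  s <- if (family == "brain_cousens") x0 else hf_crs_kernel(x0, p$a)
  denom <- 1 - pk * D
  if (abs(denom) < 1e-12 * D) {
    hf_abort("Target level unreachable: 1 - (1 - K/100)(1 + L) is zero.",
             "reparam_infeasible")
  }
  if (target$convention == "relative_to_control") {
    (p$c * (1 - D) - p$f * s) / denom
  } else {
    p$c - p$f * s / denom
  }
}

#' Solve the M stationarity relationship for f
#'
#' Returns the hormesis parameter `f` implied by requiring the dose
#' derivative of the mean function to vanish at `x = M`. Linear in `f`;
#' the closed form is used. A negative return value is allowed but flagged
#' with a warning: it means the curve has no genuine interior maximum for
#' these parameters.
#'
#' @inheritParams hm_mean
#' @param params Named parameters of the family **without** `f`, plus the
#'   target dose as `M` (> 0).
#' @return The implied `f` (scalar).
#' @export
solve_f_for_m <- function(family, params) {
  family <- hf_match_family(family)
  if (family == "loglogistic4") {
    hf_abort("The M reparameterization needs a hormetic family.",
             "capability_error")
  }
  p <- as.list(params)
  M <- p$M
  hf_assert_number(M, "M", lower = .Machine$double.xmin)
  if (p$b == 0) {
    hf_abort("Flat logistic term (b = 0): no stationarity equation to solve.",
             "stationarity_degenerate")
  }
  L <- hf_logistic_term(M, p$b, p$e)
  D <- 1 + L
  bLM <- p$b * L / M
  denom <- if (family == "brain_cousens") {
    D - p$b * L
  } else {
    hf_crs_kernel_deriv(M, p$a) * D - hf_crs_kernel(M, p$a) * bLM
  }
  if (abs(denom) < 1e-300 || !is.finite(denom)) {
    hf_abort("Stationarity equation degenerate at M (denominator zero).",
             "stationarity_degenerate")
  }
  f <- (p$d - p$c) * bLM / denom
  if (is.finite(f) && f < 0) {
    rlang::warn("Implied f is negative: no interior maximum at this M.")
  }
  f
}

#' Build a reparameterized model
#'
#' Constructs a model specification in which one natural parameter of a
#' hormetic family is replaced by a target effective dose: `d` is eliminated
#' for `ED_K`/`LDS` targets, `f` for `M`. Fitting this specification with
#' [fit_hormesis()] yields the target dose as a free parameter with a
#' standard error and confidence interval. The reparameterized mean function
#' traces exactly the same curve set as the natural family.
#'
#' @inheritParams hm_mean
#' @param target A [target_quantity()].
#' @return A `reparam_spec` list with elements `family`, `target`,
#'   `eliminated`, `par_names` (free parameters, target dose last under its
#'   name `ED_K`, `LDS` or `M`), and `mean_fn(params, dose)`.
#' @export
build_reparam_model <- function(family, target) {
  family <- hf_match_family(family)
  if (family == "loglogistic4" && target$kind %in% c("M", "LDS")) {
    hf_abort("M/LDS targets need a hormetic family.", "capability_error")
  }
  if (!inherits(target, "target_quantity")) {
    hf_abort("`target` must be a target_quantity.", "value_error")
  }
  tname <- switch(target$kind, ED_K = "ED_K", LDS = "LDS", M = "M")
  natural <- hf_param_names(family)
  if (target$kind == "M") {
    eliminated <- "f"
  } else {
    eliminated <- "d"
  }
  par_names <- c(setdiff(natural, eliminated), tname)
  mean_fn <- function(params, dose) {
    p <- as.list(params)
    if (target$kind == "M") {
      p$f <- solve_f_for_m_quiet(family, p)
    } else {
      p2 <- p
      p2$ED_K <- p[[tname]]
      p$d <- solve_d_for_edk(family, p2, target)
    }
    hm_mean(family, p, dose)
  }
  structure(list(family = family, target = target, eliminated = eliminated,
                 par_names = par_names, mean_fn = mean_fn),
            class = "reparam_spec")
}

# solve_f_for_m without the negative-f warning (used inside optimizers)
solve_f_for_m_quiet <- function(family, p) {
  suppressWarnings(solve_f_for_m(family, p))
}

#' Serialize a reparameterized model description to JSON
#'
#' @param spec A `reparam_spec` from [build_reparam_model()].
#' @return A JSON string describing family, target kind, K, convention and
#'   the eliminated natural parameter.
#' @export
reparam_to_json <- function(spec) {
  jsonlite::toJSON(list(family = spec$family, kind = spec$target$kind,
                        K = spec$target$K, convention = spec$target$convention,
                        eliminated = spec$eliminated),
                   auto_unbox = TRUE, na = "null")
}

#' Effective doses from a natural-parameter curve (numeric oracle)
#'
#' Extracts M, y_max, LDS and arbitrary ED_K values from a natural-parameter
#' curve by direct numeric search: bounded maximization for M, then root
#' finding on the inhibitory branch (doses beyond M) for LDS and ED_K, with
#' geometrically expanded brackets. This is the reference extraction route
#' against which the direct reparameterized fits are validated; it is also
#' used to seed their starting values.
#'
#' @inheritParams hm_mean
#' @param K Numeric vector of ED_K percent-inhibition levels in (0, 100).
#' @param convention Passed to [target_quantity()].
#' @param bracket_limit Upper dose bracket as a multiple of `e`.
#' @return A tibble with columns `quantity` (`"M"`, `"y_max"`, `"LDS"`,
#'   `"ED_K"`), `K` (NA except for ED rows) and `value`. For a monotone
#'   curve (f = 0) only ED_K rows are returned and requesting M/LDS is an
#'   error.
#' @export
effective_doses_numeric <- function(family, params, K = 50,
                                    convention = c("relative_to_control",
                                                   "relative_to_range"),
                                    bracket_limit = 1e6) {
  family <- hf_match_family(family)
  convention <- match.arg(convention)
  p <- hf_check_params(family, params)
  hormetic <- family != "loglogistic4" && isTRUE(p$f > 0)
  rows <- list()
  lo <- p$e * 1e-9
  hi_limit <- p$e * bracket_limit

  m <- NA_real_
  if (family != "loglogistic4") {
    if (p$f <= 0) {
      hf_abort("f <= 0: the curve has no hormetic maximum (M/LDS undefined).",
               "no_hormesis")
    }
    # locate the global max on a log-spaced grid, then polish locally
    grid <- exp(seq(log(lo), log(10 * p$e), length.out = 400))
    vals <- hm_mean(family, p, grid)
    i <- which.max(vals)
    lo_i <- grid[max(i - 1, 1)]
    hi_i <- grid[min(i + 1, length(grid))]
    m <- stats::optimize(function(x) hm_mean(family, p, x),
                         lower = lo_i, upper = hi_i, maximum = TRUE,
                         tol = 1e-12)$maximum
    y_max <- hm_mean(family, p, m)
    if (y_max <= p$d) {
      hf_abort("Curve never rises above the control mean: no hormetic zone.",
               "no_hormesis")
    }
    rows$M <- tibble(quantity = "M", K = NA_real_, value = m)
    rows$y_max <- tibble(quantity = "y_max", K = NA_real_, value = y_max)
    lds <- hf_expanding_root(function(x) hm_mean(family, p, x) - p$d,
                             lo = m, hi_start = 10 * p$e,
                             hi_limit = hi_limit, what = "LDS")
    rows$LDS <- tibble(quantity = "LDS", K = NA_real_, value = lds)
  } else {
    lds <- NA_real_
  }

  for (k in K) {
    tg <- target_quantity("ED_K", K = k, convention = convention)
    lev <- hf_target_level(tg, p$c, p$d)
    left <- if (hormetic) max(m, lds, na.rm = TRUE) else lo
    ed <- hf_expanding_root(function(x) hm_mean(family, p, x) - lev,
                            lo = left, hi_start = max(10 * p$e, left * 1.001),
                            hi_limit = hi_limit,
                            what = sprintf("ED_%g", k))
    rows[[sprintf("ED_%g", k)]] <-
      tibble(quantity = "ED_K", K = k, value = ed)
  }
  dplyr::bind_rows(rows)
}
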