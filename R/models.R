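# Mean functions and dose-derivatives for the three dose-response families.
#
# All three are built on the log-logistic decay term
#   L(x) = exp(b * (log x - log e)) = (x/e)^b,
# with the exponent clamped at +/-700 before exponentiation so extreme
# b/dose combinations stay finite.
#
#   loglogistic4:  mu(x) = c + (d - c) / (1 + L(x))
#   brain_cousens: mu(x) = c + (d - c + f*x) / (1 + L(x))
#   cedergreen:    mu(x) = c + (d - c + f*exp(-x^(-a))) / (1 + L(x))
#
# At x = 0 every family takes its analytic limit mu(0) = d (b > 0; the CRS
# stimulation term exp(-x^(-a)) -> 0). Hormesis requires f > 0. In the BC
# family f is a rate of stimulation (response per dose unit); in the CRS
# family f is an upper-bound-type parameter in response units with the shape
# of the low-dose rise governed by the exponent a > 0. Both reduce exactly
# to loglogistic4 at f = 0.

#' Model families
#'
#' Names of the supported dose-response mean function families:
#' `"brain_cousens"`, `"cedergreen"` (CRS), and `"loglogistic4"` — the
#' monotone four-parameter log-logistic that both hormetic families reduce
#' to when the hormesis parameter f is zero.
#'
#' @return Character vector of family names.
#' @export
hormesis_families <- function() c("brain_cousens", "cedergreen", "loglogistic4")

hf_match_family <- function(family) {
  match.arg(family, hormesis_families())
}

# natural parameter names of a family
hf_param_names <- function(family) {
  switch(hf_match_family(family),
    brain_cousens = c("b", "c", "d", "e", "f"),
    cedergreen    = c("b", "c", "d", "e", "f", "a"),
    loglogistic4  = c("b", "c", "d", "e"))
}

hf_check_params <- function(family, params) {
  need <- hf_param_names(family)
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    hf_abort(sprintf("Missing parameter(s) %s for family '%s'.",
                     paste(miss, collapse = ", "), family), "value_error")
  }
  p <- as.list(params)[need]
  if (any(!vapply(p, function(z) is.finite(as.numeric(z)), logical(1)))) {
    hf_abort("All parameters must be finite.", "numeric_domain")
  }
  if (p$e <= 0) hf_abort("Parameter e must be > 0.", "numeric_domain")
  if (!is.null(p$a) && p$a <= 0) {
    hf_abort("Parameter a must be > 0.", "numeric_domain")
  }
  lapply(p, as.numeric)
}

# clamped logistic decay term L(x) = (x/e)^b; x > 0
hf_logistic_term <- function(x, b, e) {
  exp(pmin(pmax(b * (log(x) - log(e)), -700), 700))
}

# CRS stimulation kernel g(x) = exp(-x^(-a)) with safe limits at 0
hf_crs_kernel <- function(x, a) {
  g <- numeric(length(x))
  pos <- x > 0
  # -x^(-a) = -exp(-a*log(x)); exponent clamped to avoid Inf*0 downstream
  g[pos] <- exp(-exp(pmin(-a * log(x[pos]), 700)))
  g
}

# d/dx of the CRS kernel: g'(x) = g(x) * a * x^(-a-1), computed in log space
hf_crs_kernel_deriv <- function(x, a) {
  stopifnot(all(x > 0))
  lg <- -exp(pmin(-a * log(x), 700))          # log g(x)
  out <- exp(lg + log(a) + (-a - 1) * log(x))
  out[!is.finite(out)] <- 0
  out
}

#' Evaluate a dose-response mean function
#'
#' Evaluates the Brain-Cousens, Cedergreen (CRS) or four-parameter
#' log-logistic mean function at the given doses. Dose 0 returns the
#' analytic limit `d` (the untreated-control mean).
#'
#' @param family One of [hormesis_families()].
#' @param params Named numeric vector or list with the family's natural
#'   parameters: `b` (slope), `c` (lower asymptote, response units), `d`
#'   (control mean), `e` (dose scale, > 0), plus `f` (hormesis parameter,
#'   BC/CRS) and `a` (CRS low-dose shape exponent, > 0).
#' @param dose Numeric vector of non-negative doses.
#' @return Numeric vector of mean responses.
#' @export
#' @examples
#' hm_mean("brain_cousens", c(b = 2, c = 0, d = 100, e = 10, f = 50), 1)
hm_mean <- function(family, params, dose) {
  family <- hf_match_family(family)
  p <- hf_check_params(family, params)
  if (any(dose < 0)) hf_abort("Doses must be non-negative.", "numeric_domain")
  out <- numeric(length(dose))
  zero <- dose == 0
  out[zero] <- p$d
  x <- dose[!zero]
  if (length(x) > 0) {
    L <- hf_logistic_term(x, p$b, p$e)
    num <- switch(family,
      loglogistic4  = p$d - p$c,
      brain_cousens = p$d - p$c + p$f * x,
      cedergreen    = p$d - p$c + p$f * hf_crs_kernel(x, p$a))
    out[!zero] <- p$c + num / (1 + L)
  }
  out
}

#' First derivative of the mean function with respect to dose
#'
#' Analytic slope of the fitted mean curve, used for locating the dose of
#' maximal stimulation M (where the slope vanishes) and in the M
#' reparameterization. Defined for strictly positive doses only (at 0 the
#' derivative exists only as a one-sided limit).
#'
#' @inheritParams hm_mean
#' @param dose Numeric vector of strictly positive doses.
#' @return Numeric vector of slopes (response per dose unit).
#' @export
hm_slope <- function(family, params, dose) {
  family <- hf_match_family(family)
  p <- hf_check_params(family, params)
  if (any(dose <= 0)) {
    hf_abort("The dose-derivative is defined for dose > 0 only.",
             "numeric_domain")
  }
  x <- dose
  L <- hf_logistic_term(x, p$b, p$e)
  D <- 1 + L
  dL <- p$b * L / x
  num <- switch(family,
    loglogistic4  = p$d - p$c,
    brain_cousens = p$d - p$c + p$f * x,
    cedergreen    = p$d - p$c + p$f * hf_crs_kernel(x, p$a))
  dnum <- switch(family,
    loglogistic4  = 0,
    brain_cousens = p$f,
    cedergreen    = p$f * hf_crs_kernel_deriv(x, p$a))
  (dnum * D - num * dL) / D^2
}
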