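# internal helpers shared across modules

# stop with a classed condition so callers can test on error class
hf_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("hormfit_", class), "hormfit_error"), ...)
}

hf_assert_number <- function(x, name, lower = -Inf, upper = Inf,
                             allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    hf_abort(sprintf("`%s` must be supplied.", name), "value_error")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    hf_abort(sprintf("`%s` must be a single finite number.", name), "value_error")
  }
  if (x < lower || x > upper) {
    hf_abort(sprintf("`%s` = %g is outside [%g, %g].", name, x, lower, upper),
             "value_error")
  }
  invisible(x)
}

# numeric jacobian of fn: R^p -> R^n by central differences
hf_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  p <- length(x)
  J <- matrix(NA_real_, nrow = length(f0), ncol = p)
  for (j in seq_len(p)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  colnames(J) <- names(x)
  J
}

# gradient of a scalar function by central differences
hf_grad <- function(fn, x, eps = 1e-6) {
  drop(hf_jacobian(function(z) fn(z), x, eps = eps))
}

# root of f on (lo, hi_start], expanding hi geometrically until sign change
# or the bracket limit; used for LDS / ED_K on the inhibitory branch
hf_expanding_root <- function(f, lo, hi_start, hi_limit, tol = 1e-10,
                              what = "root") {
  f_lo <- f(lo)
  hi <- hi_start
  repeat {
    f_hi <- f(hi)
    if (is.finite(f_lo) && is.finite(f_hi) && sign(f_lo) != sign(f_hi)) {
      r <- stats::uniroot(f, lower = lo, upper = hi,
                          f.lower = f_lo, f.upper = f_hi, tol = tol)
      return(r$root)
    }
    if (hi >= hi_limit) {
      hf_abort(
        sprintf("No sign change found for %s on (%g, %g].", what, lo, hi_limit),
        "root_not_found")
    }
    hi <- min(hi * 10, hi_limit)
  }
}
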