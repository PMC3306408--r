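test_that("solving for d pins the curve to the target level at ED_K", {
  for (family in c("cedergreen", "brain_cousens")) {
    pars <- list(b = 2, c = 3, e = 10, f = 50)
    if (family == "cedergreen") pars$a <- 1
    for (conv in c("relative_to_control", "relative_to_range")) {
      tg <- target_quantity("ED_K", K = 50, convention = conv)
      p <- c(pars, ED_K = 25)
      d <- solve_d_for_edk(family, p, tg)
      full <- c(unlist(pars), d = d)
      lev <- if (conv == "relative_to_control") 0.5 * d else 3 + 0.5 * (d - 3)
      expect_equal(hm_mean(family, full, 25), lev, tolerance = 1e-12)
    }
    # K = 0 (LDS): curve returns exactly to d, both conventions coincide
    tg0 <- target_quantity("LDS")
    p <- c(pars, ED_K = 6)
    d0 <- solve_d_for_edk(family, p, tg0)
    expect_equal(hm_mean(family, c(unlist(pars), d = d0), 6), d0,
                 tolerance = 1e-12)
  }
})

test_that("K is confined to (0, 100) for ED_K targets", {
  expect_error(target_quantity("ED_K", K = 100), class = "hormfit_value_error")
  expect_error(target_quantity("ED_K", K = 0), class = "hormfit_value_error")
  expect_error(target_quantity("ED_K"), class = "hormfit_value_error")
  expect_equal(target_quantity("LDS")$K, 0)
})

test_that("solving for f makes the curve stationary at M", {
  for (family in c("cedergreen", "brain_cousens")) {
    pars <- list(b = 2, c = 0, d = 100, e = 10, M = 2.4)
    if (family == "cedergreen") pars$a <- 1
    f <- solve_f_for_m(family, pars)
    full <- c(b = 2, c = 0, d = 100, e = 10, f = f,
              if (family == "cedergreen") c(a = 1))
    expect_lt(abs(hm_slope(family, full, 2.4)), 1e-8 * 100 / 10)
  }
})

test_that("the stationarity solution inverts the argmax (golden-section oracle)", {
  crs <- c(b = 2, c = 0, d = 100, e = 10, f = 50, a = 1)
  m_star <- optimize(function(x) hm_mean("cedergreen", crs, x),
                     c(1e-6, 100), maximum = TRUE, tol = 1e-12)$maximum
  f_rec <- solve_f_for_m("cedergreen",
                         list(b = 2, c = 0, d = 100, e = 10, a = 1,
                              M = m_star))
  expect_equal(f_rec, 50, tolerance = 1e-6)
})

test_that("degenerate stationarity is an error, negative f a warning", {
  expect_error(solve_f_for_m("cedergreen",
                             list(b = 0, c = 0, d = 100, e = 10, a = 1,
                                  M = 2)),
               class = "hormfit_stationarity_degenerate")
  # an M far out on the decay branch of a BC curve implies f < 0
  expect_warning(solve_f_for_m("brain_cousens",
                               list(b = 3, c = 0, d = 100, e = 10, M = 50)),
                 "negative")
})

test_that("reparameterized mean functions trace the natural curve set", {
  grid <- c(0, 0.05, 0.3, 1, 2.5, 8, 15, 40, 120)
  crs <- c(b = 2, c = 0, d = 100, e = 10, f = 50, a = 1)

  # CRS ED_50 spec: substitution identity against the natural curve
  tg <- target_quantity("ED_K", K = 50)
  spec <- build_reparam_model("cedergreen", tg)
  ed50 <- effective_doses_numeric("cedergreen", crs, K = 50)$value[
    effective_doses_numeric("cedergreen", crs, K = 50)$quantity == "ED_K"]
  p_re <- c(crs[c("b", "c", "e", "f", "a")], ED_K = ed50)
  expect_equal(spec$mean_fn(p_re, grid), hm_mean("cedergreen", crs, grid),
               tolerance = 1e-9)

  # BC M spec: curve derivative vanishes at the M parameter
  spec_m <- build_reparam_model("brain_cousens", target_quantity("M"))
  p_m <- c(b = 2, c = 0, d = 100, e = 10, M = 3)
  f_im <- solve_f_for_m("brain_cousens", as.list(p_m))
  h <- 1e-6 * 3
  deriv <- (spec_m$mean_fn(p_m, 3 + h) - spec_m$mean_fn(p_m, 3 - h)) / (2 * h)
  expect_lt(abs(deriv), 1e-6)

  # CRS LDS spec: curve value at x = LDS equals the implied d
  spec_l <- build_reparam_model("cedergreen", target_quantity("LDS"))
  p_l <- c(crs[c("b", "c", "e", "f", "a")], LDS = 6.3)
  d_im <- solve_d_for_edk("cedergreen", c(as.list(p_l), ED_K = 6.3),
                          target_quantity("LDS"))
  expect_equal(spec_l$mean_fn(p_l, 6.3), d_im, tolerance = 1e-10)
})

test_that("unsupported reparameterizations are capability errors", {
  expect_error(build_reparam_model("loglogistic4", target_quantity("M")),
               class = "hormfit_capability_error")
  expect_error(solve_f_for_m("loglogistic4", list(b = 2, M = 1)),
               class = "hormfit_capability_error")
})

test_that("numeric functionals: symmetric log-logistic special case", {
  ll <- c(b = 2, c = 0, d = 100, e = 10)
  out <- effective_doses_numeric("loglogistic4", ll, K = 50)
  expect_equal(out$value[out$quantity == "ED_K"], 10, tolerance = 1e-9)
  crs0 <- c(b = 2, c = 0, d = 100, e = 10, f = 0, a = 1)
  expect_error(effective_doses_numeric("cedergreen", crs0, K = numeric(0)),
               class = "hormfit_no_hormesis")
})

test_that("effective doses are ordered and ED_K increases in K", {
  for (tb in truth_bank()) {
    out <- effective_doses_numeric(tb$family, tb$params, K = c(10, 50, 90))
    p <- tb$params
    m <- out$value[out$quantity == "M"]
    lds <- out$value[out$quantity == "LDS"]
    eds <- out$value[out$quantity == "ED_K"][order(out$K[out$quantity ==
                                                           "ED_K"])]
    expect_true(0 < m && m < lds && lds < eds[1])
    expect_true(all(diff(eds) > 0))
    expect_gt(out$value[out$quantity == "y_max"], p[["d"]])
  }
})

test_that("reparam specs serialize to JSON", {
  spec <- build_reparam_model("cedergreen",
                              target_quantity("ED_K", K = 50))
  j <- jsonlite::fromJSON(reparam_to_json(spec))
  expect_equal(j$family, "cedergreen")
  expect_equal(j$K, 50)
  expect_equal(j$eliminated, "d")
})
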