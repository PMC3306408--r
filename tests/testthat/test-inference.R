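test_that("Wald/t interval arithmetic", {
  fit <- fake_fit(c(f = 2.0), ses = 0.5, df = 20)
  ci <- wald_ci(fit, "f")
  expect_equal(ci$upper - ci$estimate, 0.5 * qt(0.975, 20))
  expect_equal(ci$estimate - ci$lower, 0.5 * qt(0.975, 20))

  # degenerate SE gives a zero-width interval
  ci0 <- wald_ci(fake_fit(c(f = 2.0), ses = 0, df = 20), "f")
  expect_equal(c(ci0$lower, ci0$upper), c(2, 2))

  # large df approaches the normal half-width
  cin <- wald_ci(fake_fit(c(f = 2.0), ses = 1, df = 1e6), "f")
  expect_equal(cin$upper - cin$estimate, 1.96, tolerance = 1e-3)
})

test_that("fixed parameters are not eligible for Wald intervals", {
  d <- default_data(seed = 41)
  fit <- fit_hormesis(d, "cedergreen", a = 1)
  expect_error(wald_ci(fit, "a"), class = "hormfit_not_estimated")
  expect_error(wald_ci(fit, "zeta"), class = "hormfit_not_estimated")
})

test_that("the hormesis test follows the CI-excludes-zero rule", {
  t1 <- hormesis_test(fake_fit(c(f = 2.0), ses = 0.5, df = 20))
  expect_true(t1$significant)   # CI (0.957, 3.043) excludes zero
  t2 <- hormesis_test(fake_fit(c(f = 0.5), ses = 1.0, df = 20))
  expect_false(t2$significant)  # CI covers zero
  t3 <- hormesis_test(fake_fit(c(f = 0), ses = 0.5, df = 20))
  expect_false(t3$significant)
  # a negative f with a CI excluding zero is flagged but not "hormesis"
  t4 <- hormesis_test(fake_fit(c(f = -2), ses = 0.5, df = 20))
  expect_false(t4$significant)
  expect_true(t4$excludes_zero)
})

test_that("hormesis is not testable without a free f", {
  d <- default_data(seed = 42)
  m_fit <- fit_hormesis(d, build_reparam_model("cedergreen",
                                               target_quantity("M")),
                        a = 1)
  expect_error(hormesis_test(m_fit), class = "hormfit_not_testable")
  ll <- fit_hormesis(d, "loglogistic4")
  expect_error(hormesis_test(ll), class = "hormfit_not_testable")
})

test_that("the test works identically on ED_K-parameterized fits", {
  d <- default_data(seed = 43)
  nat <- fit_hormesis(d, "cedergreen", a = 1)
  re <- fit_hormesis(d, build_reparam_model("cedergreen",
                                            target_quantity("ED_K", K = 50)),
                     a = 1)
  tn <- hormesis_test(nat)
  tr <- hormesis_test(re)
  expect_equal(tr$f_estimate, tn$f_estimate, tolerance = 1e-3)
  expect_equal(tr$significant, tn$significant)
})

test_that("prediction at dose zero returns d with its own SE", {
  d <- default_data(seed = 44)
  fit <- fit_hormesis(d, "cedergreen", a = 1)
  pr <- predict_response(fit, 0)
  expect_equal(pr$estimate, unname(fit$estimates["d"]))
  expect_equal(pr$se, sqrt(fit$vcov["d", "d"]), tolerance = 1e-6)
})

test_that("y_max uses the predict_response code path at M", {
  d <- default_data(seed = 45)
  fit <- fit_hormesis(d, "cedergreen", a = 1)
  ym <- y_max_estimate(fit)
  pr <- predict_response(fit, ym$dose[1])
  expect_identical(ym$estimate[ym$quantity == "y_max"], pr$estimate)
  expect_identical(ym$se[ym$quantity == "y_max"], pr$se)
  expect_gt(ym$estimate[1], unname(fit$estimates["d"]))
})

test_that("direct and delta-method ED_50 intervals agree when well-conditioned", {
  d <- default_data(seed = 46)
  fit <- fit_hormesis(d, "cedergreen", a = 1)
  direct <- effective_doses(fit, K = 50, quantities = "ED")
  delta <- effective_doses(fit, K = 50, quantities = "ED",
                           source = "delta_from_natural")
  expect_equal(delta$estimate, direct$estimate, tolerance = 1e-4)
  hw_direct <- direct$upper - direct$lower
  hw_delta <- delta$upper - delta$lower
  expect_lt(abs(hw_delta - hw_direct) / hw_direct, 0.05)
})

test_that("a curve without a dip reports no pre-hormetic drop", {
  # small shape exponent: the stimulation rises before the decay acts
  d <- default_data(seed = 47, params = replace(crs_truth, "a", 0.5),
                    replicates = 6)
  fit <- fit_hormesis(d, "cedergreen", a = 0.5)
  ph <- pre_hormetic(fit)
  expect_false(ph$drop)
  expect_equal(nrow(ph$table), 0)
})

test_that("a dipping curve yields ordered pre-hormetic quantities", {
  p <- c(b = 2, c = 0, d = 100, e = 10, f = 60, a = 2)
  doses <- c(0, 0.02, 0.05, 0.1, 0.3, 1, 3, 10, 30, 100)
  d <- compute_weights(simulate_dose_response(
    "cedergreen", p, doses, replicates = 8, seed = 48))
  fit <- fit_hormesis(d, "cedergreen", a = 2)
  ph <- pre_hormetic(fit)
  expect_true(ph$drop)
  tab <- ph$table
  m_min <- tab$estimate[tab$quantity == "M_min"]
  lds_min <- tab$estimate[tab$quantity == "LDS_min"]
  expect_true(0 < m_min && m_min < lds_min && lds_min <= ph$M)
  expect_lt(tab$estimate[tab$quantity == "y_min"], fit$estimates["d"])
  expect_gt(ph$fold_m, 1)
  expect_gt(ph$fold_lds, 1)
})
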