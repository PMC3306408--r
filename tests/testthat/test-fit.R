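test_that("starting values follow the graphical protocol", {
  d <- noiseless_data()
  iv <- initial_values(d, "cedergreen")
  summ <- dose_summaries(d)
  expect_equal(unname(iv$start["d"]), summ$mean[summ$dose == 0])
  expect_equal(unname(iv$start["c"]), 0)
  # e starts at 0.8 * the dose whose mean is nearest half the control
  nz <- summ[summ$dose > 0, ]
  e_exp <- 0.8 * nz$dose[which.min(abs(nz$mean - 0.5 * summ$mean[1]))]
  expect_equal(unname(iv$start["e"]), e_exp)
  # ladder varies f outermost, then a, then b
  expect_equal(length(iv$ladder), 4 * 3 * 3)
  expect_equal(unname(vapply(iv$ladder[1:3], `[`, 1, "b")), c(1, 2, 3))

  # monotone-decreasing means start f at 0
  dm <- noiseless_data("loglogistic4", crs_truth[c("b", "c", "d", "e")])
  ivm <- initial_values(dm, "cedergreen")
  expect_equal(unname(ivm$start["f"]), 0)
})

test_that("noiseless CRS data is recovered essentially exactly", {
  d <- noiseless_data()
  fit <- fit_hormesis(d, "cedergreen", a = "free")
  expect_true(fit$converged)
  est <- c(fit$estimates, fit$fixed)[names(crs_truth)]
  expect_equal(unname(est), unname(crs_truth), tolerance = 1e-4)
  expect_lt(fit$ss_res, 1e-10)
})

test_that("the monotone reduction fits hormetic data worse than the hormetic model", {
  d <- default_data(seed = 21)
  horm <- fit_hormesis(d, "cedergreen", a = 1)
  mono <- fit_hormesis(d, "loglogistic4")
  expect_gt(mono$ss_res, horm$ss_res)
})

test_that("the reported SS_res equals its direct recomputation", {
  d <- default_data(seed = 22)
  fit <- fit_hormesis(d, "cedergreen", a = 1)
  mu <- predict(fit)
  ss <- sum(d$weight * (d$response - mu)^2)
  expect_equal(fit$ss_res, ss, tolerance = 1e-10)
  # and with unit weights the weighted SS is the ordinary SS
  d0 <- compute_weights(d, "none")
  fit0 <- fit_hormesis(d0, "cedergreen", a = 1)
  expect_equal(fit0$ss_res, sum((d0$response - predict(fit0))^2),
               tolerance = 1e-10)
})

test_that("starting values outside the bounds are a precondition error", {
  d <- default_data(seed = 23)
  expect_error(
    fit_hormesis(d, "cedergreen", a = 1,
                 start = c(b = 2, c = -5, d = 100, e = 10, f = 50)),
    class = "hormfit_value_error")
})

test_that("non-positive weights are rejected", {
  d <- default_data(seed = 24)
  d$weight[1] <- 0
  expect_error(fit_hormesis(d, "cedergreen", a = 1),
               class = "hormfit_value_error")
})

test_that("a-profiling selects the generating exponent and bookkeeps df", {
  d <- default_data(seed = 25,
                    params = replace(crs_truth, "a", 0.5), replicates = 8)
  fit <- fit_hormesis(d, "cedergreen", a = "profile",
                      a_grid = c(0.3, 0.5, 0.7))
  expect_equal(unname(fit$fixed["a"]), 0.5)
  # fixed a is not counted as estimated
  expect_equal(fit$df_res, nrow(d) - 5)
  expect_false("a" %in% names(fit$estimates))

  # a grid of one value selects that value
  fit1 <- fit_hormesis(d, "cedergreen", a = "profile", a_grid = 0.5)
  expect_equal(unname(fit1$fixed["a"]), 0.5)

  # a successful free fit leaves nothing fixed
  fit_free <- fit_hormesis(d, "cedergreen", a = "auto")
  if (length(fit_free$fixed) == 0) {
    expect_true("a" %in% names(fit_free$estimates))
    expect_equal(fit_free$df_res, nrow(d) - 6)
  }
})

test_that("natural and reparameterized fits reach the same optimum", {
  d <- default_data(seed = 26)
  nat <- fit_hormesis(d, "cedergreen", a = 1)
  spec <- build_reparam_model("cedergreen", target_quantity("ED_K", K = 50))
  re <- fit_hormesis(d, spec, a = 1)
  expect_equal(re$ss_res, nat$ss_res, tolerance = 1e-8)
  # shared parameters coincide across coordinate systems
  expect_equal(re$estimates[c("b", "e", "f")], nat$estimates[c("b", "e", "f")],
               tolerance = 1e-4)
})

test_that("fit serialization carries estimates and diagnostics", {
  d <- default_data(seed = 27)
  fit <- fit_hormesis(d, "cedergreen", a = 1)
  j <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(j$family, "cedergreen")
  expect_equal(j$estimates$d, unname(fit$estimates["d"]))
  expect_equal(j$df_res, fit$df_res)
})

test_that("BC fits with b <= 1 and positive f warn", {
  set.seed(31)
  # shallow hormetic truth drives b below 1
  d <- default_data(seed = 31, family = "brain_cousens",
                    params = c(b = 0.8, c = 0, d = 100, e = 10, f = 5))
  expect_warning(fit_hormesis(d, "brain_cousens"), "b <= 1")
})
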