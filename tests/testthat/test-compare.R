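test_that("pseudo-R2 formula and edge cases", {
  expect_equal(pseudo_r2(25, ss_corrected = 100), 0.75)
  d <- default_data(seed = 51)
  fit <- fit_hormesis(d, "cedergreen", a = 1)
  expect_equal(pseudo_r2(fit), 1 - fit$ss_res / fit$ss_corrected)
  expect_error(pseudo_r2(5, ss_corrected = 0),
               class = "hormfit_undefined_error")
})

test_that("relative bias is the signed percent formula", {
  expect_equal(relative_bias(10, 10), 0)
  expect_equal(relative_bias(10, 12), 20)
  expect_equal(relative_bias(10, 7.4), -26)
  expect_error(relative_bias(0, 5), class = "hormfit_undefined_error")
})

test_that("lack-of-fit decomposition matches a hand ANOVA", {
  # 5 doses x 2 reps, unit weights; 'fit' is frozen at known fitted values
  df <- data.frame(dose = rep(c(0, 1, 2, 4, 8), each = 2),
                   response = c(10, 12, 9, 11, 8, 10, 6, 8, 2, 4))
  d <- dose_response(df)
  fitted_at <- c("0" = 11.5, "1" = 10, "2" = 8.5, "4" = 7, "8" = 3.5)
  mu <- fitted_at[as.character(d$dose)]
  fit <- structure(list(
    data = d, ss_res = sum((d$response - mu)^2),
    df_res = nrow(d) - 3), class = "hormesis_fit")
  lof <- lack_of_fit(fit)
  # hand decomposition: pure error is 2 per dose (5 doses); the rest is LOF
  expect_equal(lof$ss_pure, 10)
  expect_equal(lof$ss_lof, fit$ss_res - 10)
  expect_equal(lof$df_pure, 5)
  expect_equal(lof$df_lof, 2)
  expect_equal(lof$F, (lof$ss_lof / 2) / (10 / 5))
  expect_equal(lof$p, pf(lof$F, 2, 5, lower.tail = FALSE))
})

test_that("a curve through the per-dose means has F = 0, p = 1", {
  df <- data.frame(dose = rep(c(0, 1, 2, 4, 8), each = 2),
                   response = c(10, 12, 9, 11, 8, 10, 6, 8, 2, 4))
  d <- dose_response(df)
  means <- dose_summaries(d)$mean
  mu <- means[match(d$dose, dose_summaries(d)$dose)]
  fit <- structure(list(data = d, ss_res = sum((d$response - mu)^2),
                        df_res = nrow(d) - 3), class = "hormesis_fit")
  lof <- lack_of_fit(fit)
  expect_equal(lof$F, 0)
  expect_equal(lof$p, 1)
})

test_that("unreplicated data cannot be tested for lack of fit", {
  df <- data.frame(dose = c(0, 1, 2, 4, 8, 16), response = runif(6))
  d <- dose_response(df)
  fit <- structure(list(data = d, ss_res = 1, df_res = 2),
                   class = "hormesis_fit")
  expect_error(lack_of_fit(fit), class = "hormfit_not_testable")
})

test_that("SS decomposition identity holds on real weighted fits", {
  for (seed in c(52, 53)) {
    d <- default_data(seed = seed)
    fit <- fit_hormesis(d, "cedergreen", a = 1)
    lof <- lack_of_fit(fit)
    expect_equal(lof$ss_lof + lof$ss_pure, fit$ss_res,
                 tolerance = 1e-10)
  }
})

test_that("case classification reproduces the documented rules", {
  m <- list(pseudo_r2 = 0.01, ss_ratio = c(0.9, 1.1))
  # only BC significant while CRS fits better: significance-driven case 2
  r <- classify_case(TRUE, FALSE, bc_ss_df = 5, crs_ss_df = 4,
                     bc_pseudo_r2 = 0.9, crs_pseudo_r2 = 0.94, margins = m)
  expect_equal(r$case, "case2_bc_better")
  expect_true(any(grepl("significance-driven", r$rationale)))
  # both significant, diagnostics within margins
  r4 <- classify_case(TRUE, TRUE, 4, 4.1, 0.95, 0.951, margins = m)
  expect_equal(r4$case, "case4_equal")
  # both significant, CRS clearly better
  r3 <- classify_case(TRUE, TRUE, 8, 4, 0.9, 0.96, margins = m)
  expect_equal(r3$case, "case3_crs_better")
  # neither significant
  r1 <- classify_case(FALSE, FALSE, 4, 4, 0.9, 0.9,
                      bc_screen_p = 0.01, crs_screen_p = 0.02, margins = m)
  expect_equal(r1$case, "case1_neither")
  expect_true(any(grepl("runs test", r1$rationale)))
  # deterministic
  expect_identical(classify_case(TRUE, TRUE, 8, 4, 0.9, 0.96, margins = m),
                   r3)
})

test_that("the full comparison report is assembled and ordered by better fit", {
  d <- default_data(seed = 54)
  cmp <- compare_hormesis_models(d, K = 50)
  expect_s3_class(cmp, "hormesis_comparison")
  expect_true(cmp$case %in% c("case1_neither", "case2_bc_better",
                              "case3_crs_better", "case4_equal"))
  expect_true(all(c("bias_pct", "abs_bias_pct", "ci_overlap") %in%
                    names(cmp$bias)))
  # the baseline model is recorded and consistent across quantities
  expect_equal(length(unique(cmp$bias$better_model)), 1)
  expect_equal(cmp$bias$abs_bias_pct, abs(cmp$bias$bias_pct))
  g <- glance(cmp)
  expect_equal(nrow(g), 1)
  expect_equal(tidy(cmp), cmp$bias)
})

test_that("comparison reports can be written to disk", {
  d <- default_data(seed = 55)
  cmp <- compare_hormesis_models(d, K = 50)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_comparison(cmp, csv_path = csv, json_path = js)
  expect_true(file.exists(csv) && file.exists(js))
  back <- jsonlite::fromJSON(js)
  expect_equal(back$case, cmp$case)
})
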