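test_that("mean functions reproduce hand-evaluated values", {
  bc <- c(b = 2, c = 0, d = 100, e = 10, f = 50)
  # midpoint of the monotone curve at x = e when f = 0
  expect_equal(hm_mean("brain_cousens", replace(bc, "f", 0), 10), 50)
  expect_equal(hm_mean("loglogistic4", bc[c("b", "c", "d", "e")], 10), 50)
  # hand evaluation: (100 + 50*1)/(1 + (1/10)^2)
  expect_equal(hm_mean("brain_cousens", bc, 1), 150 / 1.01)
  # CRS hand evaluation: (100 + 50*exp(-1))/(1 + 0.01)
  crs <- c(bc, a = 1)
  expect_equal(hm_mean("cedergreen", crs, 1), (100 + 50 * exp(-1)) / 1.01)
  # control limit at dose 0
  expect_equal(hm_mean("brain_cousens", bc, 0), 100)
  expect_equal(hm_mean("cedergreen", crs, 0), 100)
  expect_equal(hm_mean("loglogistic4", bc[c("b", "c", "d", "e")], 0), 100)
})

test_that("both hormetic families reduce exactly to the log-logistic at f = 0", {
  set.seed(11)
  grid <- c(0, exp(seq(log(1e-4), log(1e4), length.out = 100)))
  for (i in 1:25) {
    p <- c(b = runif(1, 0.5, 5), c = runif(1, 0, 20),
           d = runif(1, 50, 150), e = 10^runif(1, -1, 2), f = 0,
           a = runif(1, 0.1, 2))
    ll <- hm_mean("loglogistic4", p[c("b", "c", "d", "e")], grid)
    expect_equal(hm_mean("brain_cousens", p[-6], grid), ll, tolerance = 1e-14)
    expect_equal(hm_mean("cedergreen", p, grid), ll, tolerance = 1e-14)
  }
})

test_that("evaluation converges continuously to d near dose zero", {
  crs <- c(b = 2, c = 0, d = 100, e = 10, f = 50, a = 0.5)
  vals <- hm_mean("cedergreen", crs, 10^-(3:12))
  expect_true(all(abs(vals - 100) < c(abs(vals[1] - 100) + 1e-12)))
  expect_equal(hm_mean("cedergreen", crs, 1e-12), 100, tolerance = 1e-6)
  bc <- c(b = 2, c = 0, d = 100, e = 10, f = 50)
  expect_equal(hm_mean("brain_cousens", bc, 1e-12), 100, tolerance = 1e-6)
})

test_that("BC curves are equivariant under dose rescaling", {
  p <- c(b = 2.5, c = 5, d = 100, e = 10, f = 5)
  s <- 7.3
  x <- c(0, 0.1, 1, 5, 20, 100)
  p2 <- p; p2["e"] <- s * p["e"]; p2["f"] <- p["f"] / s
  expect_equal(hm_mean("brain_cousens", p2, s * x),
               hm_mean("brain_cousens", p, x), tolerance = 1e-12)
})

test_that("extreme slopes and doses stay finite", {
  p <- c(b = 200, c = 0, d = 100, e = 10, f = 50, a = 2)
  expect_true(all(is.finite(hm_mean("cedergreen", p, c(1e-300, 1e300)))))
  expect_true(all(is.finite(hm_mean("brain_cousens", p[-6],
                                    c(1e-300, 1e6)))))
})

test_that("analytic dose-derivative matches central differences", {
  cases <- list(
    list(family = "brain_cousens",
         p = c(b = 2, c = 0, d = 100, e = 10, f = 50)),
    list(family = "cedergreen",
         p = c(b = 1.3, c = 4, d = 90, e = 8, f = 40, a = 0.6)),
    list(family = "loglogistic4", p = c(b = 3, c = 2, d = 80, e = 5)))
  for (cs in cases) {
    for (x in c(0.05, 0.7, 3, 15, 80)) {
      h <- 1e-4 * x
      f <- function(z) hm_mean(cs$family, cs$p, z)
      # fourth-order central difference to push truncation error below 1e-6
      fd <- (8 * (f(x + h) - f(x - h)) - (f(x + 2 * h) - f(x - 2 * h))) /
        (12 * h)
      expect_equal(hm_slope(cs$family, cs$p, x), fd, tolerance = 1e-6)
    }
  }
})

test_that("slope properties: zero at the maximum, negative for monotone decay", {
  crs <- c(b = 2, c = 0, d = 100, e = 10, f = 50, a = 1)
  m <- optimize(function(x) hm_mean("cedergreen", crs, x), c(1e-6, 100),
                maximum = TRUE, tol = 1e-12)$maximum
  expect_lt(abs(hm_slope("cedergreen", crs, m)), 1e-8 * 100 / 10)
  ll <- c(b = 2, c = 0, d = 100, e = 10)
  expect_true(all(hm_slope("loglogistic4", ll, c(0.1, 1, 10, 100)) < 0))
})

test_that("domain violations raise classed errors", {
  crs <- c(b = 2, c = 0, d = 100, e = 10, f = 50, a = -1)
  expect_error(hm_mean("cedergreen", crs, 1),
               class = "hormfit_numeric_domain")
  ok <- replace(crs, "a", 1)
  expect_error(hm_mean("cedergreen", replace(ok, "e", -5), 1),
               class = "hormfit_numeric_domain")
  expect_error(hm_mean("cedergreen", replace(ok, "d", NaN), 1),
               class = "hormfit_numeric_domain")
  expect_error(hm_slope("cedergreen", ok, 0),
               class = "hormfit_numeric_domain")
  expect_error(hm_mean("cedergreen", ok, -1),
               class = "hormfit_numeric_domain")
})
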