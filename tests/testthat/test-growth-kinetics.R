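test_that("noiseless exponentials are recovered to machine precision", {
  t <- seq(0, 72, 12)
  for (r in c(0.02, 0.035, -0.01)) {
    f <- fit_exponential(list(times = t, counts = 100 * exp(r * t)))
    expect_lt(abs(f$rate_hat - r), 1e-6)
    expect_lt(abs(f$n0_hat - 100), 1e-4)
    expect_true(f$converged)
    expect_lt(f$rss, 1e-8 * sum((100 * exp(r * t))^2))
    expect_lte(f$rss, f$rss_init)
  }
})

test_that("exact doubling data give the closed-form rate ln2/24", {
  f <- fit_exponential(list(times = c(0, 24, 48), counts = c(100, 200, 400)))
  expect_equal(f$rate_hat, log(2) / 24, tolerance = 1e-9)
})

test_that("rate estimates are unbiased and SEs calibrated under CV noise", {
  fits <- lapply(1:200, function(s) {
    fit_exponential(gen_growth_counts(growth_params(n0 = 100, rate = 0.03,
                                                    noise_cv = 0.05, seed = s)))
  })
  rates <- vapply(fits, `[[`, numeric(1), "rate_hat")
  ses <- vapply(fits, `[[`, numeric(1), "rate_se")
  expect_lt(abs(mean(rates) - 0.03) / 0.03, 0.02)
  expect_lt(abs(mean(ses) - sd(rates)) / sd(rates), 0.25)
})

test_that("fit agrees with an independent Levenberg-Marquardt solver", {
  skip_if_not_installed("minpack.lm")
  gc <- gen_growth_counts(growth_params(n0 = 120, rate = 0.025,
                                        noise_cv = 0.08, seed = 5))
  f <- fit_exponential(gc)
  ref <- minpack.lm::nlsLM(counts ~ n0 * exp(r * times),
                           data = data.frame(times = gc$times, counts = gc$counts),
                           start = list(n0 = 100, r = 0.02))
  expect_equal(f$rate_hat, unname(coef(ref)["r"]), tolerance = 1e-6)
  expect_equal(f$n0_hat, unname(coef(ref)["n0"]), tolerance = 1e-4)
})

test_that("fit obeys rescaling and time-shift covariance", {
  t <- seq(0, 72, 12)
  y <- 100 * exp(0.02 * t) * (1 + 0.02 * sin(seq_along(t)))
  f1 <- fit_exponential(list(times = t, counts = y))
  f2 <- fit_exponential(list(times = t, counts = 5 * y))
  expect_equal(f2$rate_hat, f1$rate_hat, tolerance = 1e-8)
  expect_equal(f2$n0_hat, 5 * f1$n0_hat, tolerance = 1e-6)
  f3 <- fit_exponential(list(times = t + 10, counts = y))
  expect_equal(f3$rate_hat, f1$rate_hat, tolerance = 1e-8)
  expect_equal(f3$n0_hat, f1$n0_hat * exp(-f1$rate_hat * 10), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_exponential(list(times = c(0, 12, 24), counts = c(0, 0, 0))),
               "all counts")
  expect_error(fit_exponential(list(times = c(0, 12), counts = c(1, 2))),
               ">= 3 timepoints")
  expect_error(fit_exponential(list(times = c(0, 12, 24), counts = c(1, NA, 2))),
               "non-finite")
})

test_that("growth_fit methods are mutually consistent", {
  gc <- gen_growth_counts(growth_params(seed = 3))
  f <- fit_exponential(gc)
  expect_named(coef(f), c("n0", "rate"))
  expect_equal(unname(coef(f)["n0"]), f$n0_hat)
  expect_equal(residuals(f), f$counts - fitted(f))
  expect_equal(predict(f, 0), f$n0_hat)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(length(f$times), 3L))
  out <- capture.output(print(summary(f)))
  expect_true(any(grepl("doubling", out)))
})

test_that("relative growth rate handles treated, equal and shrinking cases", {
  expect_equal(relative_growth_rate(0.03, 0.03), 1.0)
  expect_equal(relative_growth_rate(0.015, 0.030), 0.5)
  expect_lt(relative_growth_rate(-0.01, 0.02), 0)
  expect_warning(out <- relative_growth_rate(0.01, -0.02), "undefined")
  expect_true(is.na(out))
  # generator ground truth through the full fit: dose = IC50 halves the rate
  gp <- growth_params(n0 = 1e5, rate = 0.03, noise_cv = 0)
  ds <- gen_dose_response(gp, doses = c(0, 0.32, 1), hill_ic50 = 0.32)
  fits <- lapply(ds, fit_exponential)
  expect_equal(relative_growth_rate(fits[["0.32"]], fits[["0"]]), 0.5,
               tolerance = 1e-5)
})
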