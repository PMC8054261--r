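# Hierarchical growth-rate model ------------------------------------------

test_that("zero-noise tables pin the posterior at the deterministic truth", {
  sp <- effects_table_spec(exp_sd = 0,
                           residual_sd_by_plate = c(plastic = 0,
                                                    softwell_0.2kPa = 0,
                                                    softwell_2kPa = 0),
                           n_experiments = 3L, n_replicates = 2L)
  tab <- gen_effects_table(sp)
  fit <- suppressWarnings(fit_hierarchical_growth_model(
    tab, hier_model_spec(contrasts = stiffness_contrast,
                         iter = 1500L, warmup = 400L, seed = 2L)))
  est <- fit$summary$mean[fit$summary$param == "stiff"]
  expect_lt(abs(est - 0.006), 1e-4)
})

test_that("duplicate-seeded runs are identical and mixing is diagnosed", {
  tab <- gen_effects_table(effects_table_spec(seed = 11L))
  spec <- hier_model_spec(contrasts = stiffness_contrast, seed = 3L)
  f1 <- fit_hierarchical_growth_model(tab, spec)
  f2 <- fit_hierarchical_growth_model(tab, spec)
  expect_identical(f1$summary, f2$summary)
  expect_true(f1$converged)
  expect_true(all(f1$summary$rhat < 1.05))
  expect_true(all(f1$summary$ess > 400))
  # planted contrast sits inside its own credible interval
  r <- f1$summary[f1$summary$param == "stiff", ]
  expect_true(r$lower <= 0.006 && 0.006 <= r$upper)
  # residual scales recovered on the right order
  sp_est <- f1$summary$mean[f1$summary$param == "sigma_resid:plastic"]
  expect_lt(abs(sp_est - 0.002) / 0.002, 0.5)
})

test_that("posterior mean tracks OLS as priors widen", {
  tab <- gen_effects_table(effects_table_spec(seed = 21L))
  ols <- unname(coef(lm(rate ~ cell + plate, data = tab))[1])
  w <- 0.02 * sd(tab$rate)
  tight <- suppressWarnings(fit_hierarchical_growth_model(
    tab, hier_model_spec(prior_scale_coef = w, iter = 1500L, warmup = 400L,
                         seed = 5L)))
  wide <- suppressWarnings(fit_hierarchical_growth_model(
    tab, hier_model_spec(prior_scale_coef = 100 * w, iter = 1500L,
                         warmup = 400L, seed = 5L)))
  mu_t <- tight$summary$mean[tight$summary$param == "mu"]
  mu_w <- wide$summary$mean[wide$summary$param == "mu"]
  expect_lt(abs(mu_w - ols), abs(mu_t - ols))
  expect_lt(abs(mu_w - ols), 0.002)
})

test_that("hierarchical point estimates agree with an lme4 cross-check", {
  skip_if_not_installed("lme4")
  tab <- gen_effects_table(effects_table_spec(seed = 31L))
  fit <- fit_hierarchical_growth_model(
    tab, hier_model_spec(contrasts = stiffness_contrast, seed = 4L))
  ref <- lme4::lmer(rate ~ cell + plate + (1 | experiment), data = tab)
  b <- lme4::fixef(ref)
  ref_contrast <- unname(b["platesoftwell_2kPa"] - b["platesoftwell_0.2kPa"])
  est <- fit$summary$mean[fit$summary$param == "stiff"]
  expect_lt(abs(est - ref_contrast), 1.5e-3)
})

test_that("non-identifiable designs fail with the offending level named", {
  tab <- gen_effects_table(effects_table_spec(seed = 1L))
  tab$plate <- factor(tab$plate,
                      levels = c(unique(tab$plate), "softwell_20kPa"))
  expect_error(fit_hierarchical_growth_model(tab, hier_model_spec()),
               "softwell_20kPa")
  one <- gen_effects_table(effects_table_spec(n_experiments = 1L))
  expect_error(fit_hierarchical_growth_model(one, hier_model_spec()),
               ">= 2 experiments")
})

# IC50-difference model ----------------------------------------------------

test_that("identical IC50s across groups give a fold change of one", {
  tab <- data.frame(ic50 = rep(c(0.5, 0.52, 0.48), 3),
                    cell = "HCT116",
                    o2 = rep(c("21%", "1%", "0.1%"), each = 3))
  fit <- suppressWarnings(fit_ic50_difference_model(
    tab, prior_scale_delta = 0.05, iter = 1500L, warmup = 400L, seed = 6L))
  expect_true(all(abs(fit$summary$fold_mean - 1) < 0.05))
})

test_that("single cell line with two O2 levels reports one difference", {
  tab <- gen_ic50_table(fold = c("1%" = 1.3), n_per_group = 4L, seed = 2L)
  fit <- suppressWarnings(fit_ic50_difference_model(tab, iter = 1500L,
                                                    warmup = 400L, seed = 2L))
  expect_identical(nrow(fit$summary), 1L)
  expect_identical(fit$summary$o2, "1%")
})

test_that("censored (non-positive) IC50s are excluded with a warning", {
  tab <- gen_ic50_table(seed = 3L)
  tab$ic50[c(1, 7)] <- c(NA, -1)
  expect_warning(fit_ic50_difference_model(tab, iter = 1200L, warmup = 300L,
                                           seed = 3L),
                 "censored")
  tab2 <- gen_ic50_table(n_per_group = 2L, seed = 4L)
  tab2$ic50[1] <- NA # drops a group below 2 replicates
  expect_error(suppressWarnings(fit_ic50_difference_model(tab2)),
               ">= 2 replicate")
  expect_error(fit_ic50_difference_model(gen_ic50_table(seed = 5L),
                                         reference = "5%"),
               "reference")
})

test_that("a planted 1.7-fold hypoxia effect is recovered", {
  tab <- gen_ic50_table(seed = 12L)
  fit <- fit_ic50_difference_model(tab, seed = 12L)
  r <- fit$summary[fit$summary$o2 == "0.1%", ]
  expect_true(r$fold_lower <= 1.7 && 1.7 <= r$fold_upper)
  expect_true(fit$converged)
  # the no-effect level stays near fold 1
  r1 <- fit$summary[fit$summary$o2 == "1%", ]
  expect_true(r1$fold_lower <= 1 && 1 <= r1$fold_upper)
})
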