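test_that("noiseless count series follow the rounded exponential exactly", {
  gc <- gen_growth_counts(growth_params(n0 = 100, rate = 0.03,
                                        times = seq(0, 72, 12), noise_cv = 0))
  expect_equal(gc$counts, round(100 * exp(0.03 * seq(0, 72, 12))))
  expect_identical(gc$counts[1:3], c(100, 143, 205))
  # zero rate: constant population
  gc0 <- gen_growth_counts(growth_params(n0 = 100, rate = 0, noise_cv = 0))
  expect_true(all(gc0$counts == 100))
  # ratio property: counts(t2)/counts(t1) = exp(r dt) up to rounding
  expect_true(all(abs(gc$counts - 100 * exp(0.03 * gc$times)) <= 0.5))
})

test_that("multiplicative lognormal noise has unit mean at the stated CV", {
  means <- vapply(1:1000, function(s) {
    gen_growth_counts(growth_params(n0 = 100, rate = 0.03, times = c(0, 24),
                                    noise_cv = 0.05, seed = s))$counts[2]
  }, numeric(1))
  expect_lt(abs(mean(means) - 100 * exp(0.72)) / (100 * exp(0.72)), 0.01)
})

test_that("growth generator rejects invalid designs with informative errors", {
  expect_error(growth_params(times = c(0, 24, 24, 48)), "index 3")
  expect_error(growth_params(times = c(0, 24, 12)), "strictly increasing")
  expect_error(growth_params(n0 = 0), "n0")
  expect_error(growth_params(noise_cv = -1), "noise_cv")
})

test_that("generators are bit-reproducible for a fixed seed", {
  p <- growth_params(noise_cv = 0.1, seed = 99L)
  expect_identical(gen_growth_counts(p)$counts, gen_growth_counts(p)$counts)
  sp <- tiny_scene_params(5L)
  s1 <- gen_well_scene(sp); s2 <- gen_well_scene(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$cells, s2$cells)
  es <- effects_table_spec(seed = 7L)
  expect_identical(gen_effects_table(es)$rate, gen_effects_table(es)$rate)
})

test_that("dose series implements the Hill attenuation with exact anchors", {
  gp <- growth_params(n0 = 100, rate = 0.03, noise_cv = 0)
  ds <- gen_dose_response(gp, doses = c(0, 0.32, 1), hill_ic50 = 0.32,
                          hill_slope = 1)
  tr <- attr(ds, "truth")
  expect_identical(tr$rates[1], 0.03)        # untreated anchor
  expect_equal(tr$rates[2], 0.015)           # Hill midpoint at d = IC50
  # Fig-style 3-fold dilution grid: rates strictly decreasing in dose
  ds2 <- gen_dose_response(gp, hill_ic50 = 0.32, hill_slope = 1)
  expect_true(all(diff(attr(ds2, "truth")$rates) < 0))
  expect_error(gen_dose_response(gp, hill_ic50 = -1), "hill_ic50")
  expect_error(gen_dose_response(gp, doses = c(0.1, 1)), "dose 0")
})

test_that("well scenes carry exact bookkeeping and ground truth", {
  sc <- gen_well_scene(tiny_scene_params(2L))
  expect_identical(sum(sc$cells$on_disc), 30L)
  expect_identical(sum(!sc$cells$on_disc), 12L)
  expect_false(sc$meta$no_texture_contrast)
  # degenerate no-contrast scene is flagged, not rejected
  sc0 <- gen_well_scene(tiny_scene_params(2L, texture_sd_on = 15,
                                          texture_sd_off = 15))
  expect_true(sc0$meta$no_texture_contrast)
  # capacity guard
  expect_error(gen_well_scene(tiny_scene_params(1L, n_cells_on = 1e6)),
               "capacity")
  # disc must stay inside the image unless clipping is allowed
  expect_error(disc_scene_params(disc_center = c(10, 10)), "clipped")
})

test_that("scene texture contrast and mask rasterization match the model", {
  sc <- gen_well_scene(disc_scene_params(seed = 3L))
  resp <- local_std_filter(sc$image, 9)
  expect_gt(mean(resp[sc$mask]), mean(resp[!sc$mask]))
  # rasterized disc area within 1% of pi r^2 (radius > 100 px here)
  r <- sc$params$disc_radius
  expect_gt(r, 100)
  expect_lt(abs(sum(sc$mask) - pi * r^2) / (pi * r^2), 0.01)
})

test_that("effects tables realize the declared mixed-effects structure", {
  # deterministic limit: y equals the declared means exactly
  sp0 <- effects_table_spec(exp_sd = 0,
                            residual_sd_by_plate = c(plastic = 0,
                                                     softwell_0.2kPa = 0,
                                                     softwell_2kPa = 0),
                            n_experiments = 2L, n_replicates = 2L)
  tab0 <- gen_effects_table(sp0)
  expected <- sp0$mu + sp0$cell_effects[tab0$cell] + sp0$plate_effects[tab0$plate]
  expect_equal(tab0$rate, unname(expected))

  # law of large numbers: planted plate contrast recovered at n = 1e4
  sp1 <- effects_table_spec(n_experiments = 2L, n_replicates = 10000L,
                            seed = 31L)
  tab1 <- gen_effects_table(sp1)
  d <- mean(tab1$rate[tab1$plate == "softwell_2kPa"]) -
    mean(tab1$rate[tab1$plate == "softwell_0.2kPa"])
  expect_lt(abs(d - 0.006), 5e-4)

  # per-plate residual SDs recovered within 10% at n = 1e4
  sp2 <- effects_table_spec(cell_levels = "HCT116",
                            cell_effects = c(HCT116 = 0),
                            plate_levels = c("plastic", "softwell_2kPa"),
                            plate_effects = c(plastic = 0, softwell_2kPa = 0),
                            residual_sd_by_plate = c(plastic = 0.001,
                                                     softwell_2kPa = 0.01),
                            exp_sd = 0, n_experiments = 1L,
                            n_replicates = 10000L, seed = 8L)
  tab2 <- gen_effects_table(sp2)
  expect_lt(abs(sd(tab2$rate[tab2$plate == "plastic"]) - 0.001) / 0.001, 0.10)
  expect_lt(abs(sd(tab2$rate[tab2$plate == "softwell_2kPa"]) - 0.01) / 0.01, 0.10)

  expect_error(effects_table_spec(plate_effects = c(plastic = 0)),
               "missing level")
})

test_that("planted IC50 tables put the fold change where declared", {
  tab <- gen_ic50_table(sdlog = 0, seed = 1L)
  expect_equal(unique(tab$ic50[tab$o2 == "0.1%"]) /
                 unique(tab$ic50[tab$o2 == "21%"]), 1.7)
  expect_equal(nrow(tab), 18L)
})
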