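# discgrowth

Quantitative analysis of high-content imaging screens in which colorectal
cancer (CRC) cells grow under controlled microenvironmental perturbations —
oxygen tension, substrate stiffness, drug dose — including growth directly
on decellularized liver extracellular-matrix (ECM) scaffold discs confined
in 96-well plates. The package is aimed at imaging labs and computational
groups who have per-well scan images and nuclear-detection tables (well,
time, centroid, live/dead) exported from a high-content platform and want
reproducible growth rates, dose–response summaries and comparative
statistics out the other end.

## What it computes

- **Disc segmentation.** ECM material has higher local intensity variance
  than the empty well bottom. A local standard-deviation filter (followed
  by a median filter) finds the textured core of the disc; comparison
  against an empty-well **light profile** adds candidate on-disc pixels;
  dilation, reconstruction from the texture core, hole filling and erosion
  produce the final mask. The controlling parameters (texture kernel,
  candidate threshold, structuring-element size) are swept and each
  candidate mask is scored against the known disc geometry (6 mm diameter):
  `S = |area − expected| / expected + w · (1 − 4π·area/perimeter²)`,
  lowest score wins, full ranking returned for manual override.
- **Cell co-registration.** Each detected centroid is overlaid on the mask
  (round-half-up pixel lookup) and labelled on-disc or off-disc; on-disc
  live counts per timepoint form the growth curve.
- **Growth kinetics.** Live-count series are fit by unweighted nonlinear
  least squares to `N(t) = N₀·e^{rt}` with a damped (Levenberg–Marquardt)
  iteration; `r` (per hour) is unconstrained in sign. Relative growth rate
  is `r_treated / r_control`.
- **IC50.** The dose at which the relative growth rate crosses 0.5, by
  linear interpolation of relative rate against log₁₀(dose) between the
  first bracketing pair of positive doses; curves that never cross are
  censored `above_max` / `below_min`.
- **Statistics.** Exact two-sided sign test (doubled binomial tail, capped
  at 1); two-sided Welch *t* tests; a hierarchical Bayesian model of growth
  rates with fixed cell-type and plate-type effects, a random
  experiment-date effect and per-plate-type residual variances under
  zero-centered Cauchy / half-Cauchy priors; and an empirical-Bayes model
  of log-IC50 differences between oxygen conditions reporting posterior
  fold changes `e^δ` with symmetric 95% credible intervals. Both models are
  sampled by adaptive Metropolis-within-Gibbs with split R-hat / ESS
  convergence gates.
- **Synthetic data.** Seeded generators for well scenes (disc texture,
  vignetting light profile, nuclear spots, camera noise), count series
  (multiplicative lognormal noise of given CV), Hill-attenuated dilution
  series, and multi-experiment rate/IC50 tables — each returning its ground
  truth, so every stage of the pipeline is testable end-to-end.

## Worked example

```r
library(discgrowth)

# a synthetic well: image + light profile + ground truth
scene <- gen_well_scene(disc_scene_params(seed = 11))
mask  <- segment_disc(scene$image, scene$profile)
mask
#> Disc mask: 93721 px foreground (63.6% of 384 x 384 image)
round(mask_iou(mask, scene$mask), 3)
#> [1] 0.931

# co-register detections with the mask
reg <- register_cells(scene$cells[, 1:5], mask)
registration_summary(reg)
#>   time_h on_live on_dead off_live off_dead total
#> 1      0      53       7        9        1    70

# dose-response growth fits and IC50
gp   <- growth_params(n0 = 100, rate = 0.03, noise_cv = 0.05, seed = 11)
fits <- lapply(gen_dose_response(gp, hill_ic50 = 0.32), fit_exponential)
fits[["0"]]
#> Exponential growth fit: N(t) = n0 * exp(r t)
#>   n0   = 113.8 (se 12.68)
#>   rate = 0.02695 /h (se 0.002326)
#>   rss = 7239 over 7 timepoints; converged in 7 iterations
ic50_log_interp(build_curve(fits))
#> IC50 = 0.4163 uM (bracket 0.185-0.555 uM)

# eight growth-rate comparisons all trending one way
sign_test_two_sided(rep(-1, 8))
#> Exact two-sided sign test: 0 of 8 differences positive, P = 0.008

# posterior fold change of IC50 under deep hypoxia (planted 1.7-fold)
fit <- fit_ic50_difference_model(gen_ic50_table(seed = 11), seed = 11)
fit
#> IC50 differences vs 21% (log-scale model, converged)
#>   HCT116 @ 1% O2: fold change 0.957 (95% CI 0.714-1.24)
#>   HCT116 @ 0.1% O2: fold change 1.75 (95% CI 1.29-2.28)
```

The untreated fit recovers the generating rate 0.03/h within its standard
error; the interpolated IC50 sits above the planted 0.32 uM because linear
interpolation on four log-spaced points carries a small convexity bias
(bounded in the tests); the sign test reproduces the exact
`2·(1/2)⁸ = 0.0078` tail; and the hypoxia model's credible interval covers
the planted 1.7-fold effect.

`run_pipeline("config.yaml")` (see `inst/extdata/demo-config.yaml`) chains
every stage — scene, segmentation sweep, registration, fitting, IC50,
statistics — writing per-stage artifacts, and a manifest of MD5 checksums
that makes reruns verifiable; `demo_pipeline()` runs the shipped demo.

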