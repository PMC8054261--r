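#' Parameters for a synthetic exponential growth curve
#'
#' Bundles the ground-truth parameters of the exponential live-cell count
#' model `N(t) = n0 * exp(rate * t)` together with the sampling design and
#' a noise level, for use by [gen_growth_counts()].
#'
#' @param n0 initial live-cell count (> 0).
#' @param rate specific growth rate per hour; may be negative for
#'   cytotoxic conditions.
#' @param times sampling times in hours, strictly increasing, all >= 0.
#'   Default covers the 0--72 h horizon at 12 h intervals.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   count noise (>= 0; 0 gives noiseless rounded counts).
#' @param seed integer RNG seed.
#' @return an object of class `"growth_params"`.
#' @seealso [gen_growth_counts()]
#' @export
growth_params <- function(n0 = 100, rate = 0.03, times = seq(0, 72, by = 12),
                          noise_cv = 0.05, seed = 1L) {
  stopifnot(is.numeric(n0), length(n0) == 1L, is.finite(n0),
            is.numeric(rate), length(rate) == 1L, is.finite(rate),
            is.numeric(times), length(times) >= 1L, all(is.finite(times)),
            is.numeric(noise_cv), length(noise_cv) == 1L, is.finite(noise_cv))
  if (n0 <= 0) stop("n0 must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (any(times < 0)) stop("times must be >= 0")
  check_strictly_increasing(times)
  structure(list(n0 = n0, rate = rate, times = as.numeric(times),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "growth_params")
}

check_strictly_increasing <- function(times) {
  if (length(times) > 1L) {
    d <- diff(times)
    if (any(d <= 0)) {
      i <- which(d <= 0)[1L] + 1L
      stop(sprintf("times must be strictly increasing; offending index %d (t = %g after %g)",
                   i, times[i], times[i - 1L]))
    }
  }
  invisible(times)
}

#' Construct a growth curve
#'
#' A growth curve is the (time, live count) series for one condition; the
#' container used throughout the package for fitting and registration
#' output.
#'
#' @param times hours, strictly increasing.
#' @param counts nonnegative live-cell counts, same length as `times`.
#' @param condition optional named list identifying the condition (cell
#'   line, oxygen, substrate, dose, experiment date ...).
#' @param truth optional named list of ground-truth generator parameters.
#' @return an object of class `"growth_curve"`: a list with elements
#'   `times`, `counts`, `condition`, `truth`.
#' @export
growth_curve <- function(times, counts, condition = list(), truth = NULL) {
  stopifnot(is.numeric(times), is.numeric(counts),
            length(times) == length(counts))
  check_strictly_increasing(times)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  structure(list(times = as.numeric(times), counts = as.numeric(counts),
                 condition = condition, truth = truth),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("Growth curve:", length(x$times), "timepoints,",
      sprintf("t = %g..%g h, counts %g..%g", min(x$times), max(x$times),
              min(x$counts), max(x$counts)), "\n")
  if (length(x$condition))
    cat("  condition:", paste(names(x$condition), unlist(x$condition),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.growth_curve <- function(x, ...) {
  data.frame(time_h = x$times, count = x$counts)
}

#' Generate a synthetic live-cell count series
#'
#' Simulates the count series the imaging platform would report for one
#' well: expected counts `n0 * exp(rate * t)` perturbed by multiplicative
#' lognormal noise with the requested coefficient of variation, rounded to
#' whole cells and clipped at zero.  The lognormal factors have mean
#' exactly 1, so noisy counts are unbiased for the expected trajectory.
#'
#' With `noise_cv = 0` the factors are identically 1 and the output is the
#' rounded noiseless exponential.  An optional Poisson mode replaces the
#' lognormal factor with Poisson sampling about the expected count.
#'
#' @param params a [growth_params()] object.
#' @param noise one of `"lognormal"` (default) or `"poisson"`.
#' @return a [growth_curve()] whose `truth` records the generator
#'   parameters.
#' @examples
#' gc <- gen_growth_counts(growth_params(n0 = 100, rate = 0.03, noise_cv = 0))
#' gc$counts
#' @export
gen_growth_counts <- function(params, noise = c("lognormal", "poisson")) {
  stopifnot(inherits(params, "growth_params"))
  noise <- match.arg(noise)
  mu <- params$n0 * exp(params$rate * params$times)
  counts <- with_substream(params$seed, "growth_counts", {
    if (noise == "poisson") {
      as.numeric(stats::rpois(length(mu), mu))
    } else if (params$noise_cv == 0) {
      round(mu)
    } else {
      s2 <- log(1 + params$noise_cv^2)
      m <- rlnorm(length(mu), meanlog = -s2 / 2, sdlog = sqrt(s2))
      round(mu * m)
    }
  })
  growth_curve(params$times, pmax(counts, 0),
               truth = list(n0 = params$n0, rate = params$rate,
                            noise_cv = params$noise_cv, noise = noise))
}

#' Generate a synthetic oxaliplatin-style dilution series
#'
#' Simulates one dose-response experiment: for each dose `d` the growth
#' rate is attenuated by a Hill curve,
#' `rate(d) = rate * (1 - d^h / (d^h + ic50^h))`, so the ground-truth IC50
#' of the relative-rate curve equals `hill_ic50` by construction, and a
#' count series is generated at that rate.  The default dose grid is the
#' 3-fold dilution series used on oxaliplatin screens
#' (0, 0.062, 0.185, 0.555, 1.667, 5 uM).
#'
#' @param growth a [growth_params()] object for the untreated (dose 0) well.
#' @param doses micromolar doses, must include 0 (the untreated anchor).
#' @param hill_ic50 ground-truth IC50 in uM (> 0).
#' @param hill_slope Hill coefficient h (> 0).
#' @param seed integer seed; each dose draws from its own substream.
#' @return a named list of [growth_curve()] objects keyed by dose (class
#'   `"dose_series"`), with attribute `truth` holding `hill_ic50`,
#'   `hill_slope` and the per-dose true rates.
#' @export
gen_dose_response <- function(growth,
                              doses = c(0, 0.062, 0.185, 0.555, 1.667, 5),
                              hill_ic50 = 0.32, hill_slope = 1,
                              seed = growth$seed) {
  stopifnot(inherits(growth, "growth_params"), is.numeric(doses))
  if (any(doses < 0)) stop("doses must be >= 0")
  if (!any(doses == 0)) stop("dose 0 (untreated reference) must be present")
  if (hill_ic50 <= 0) stop("hill_ic50 must be > 0")
  if (hill_slope <= 0) stop("hill_slope must be > 0")
  doses <- sort(unique(as.numeric(doses)))
  rates <- vapply(doses, function(d) {
    growth$rate * (1 - d^hill_slope / (d^hill_slope + hill_ic50^hill_slope))
  }, numeric(1))
  curves <- lapply(seq_along(doses), function(i) {
    p <- growth_params(n0 = growth$n0, rate = rates[i], times = growth$times,
                       noise_cv = growth$noise_cv,
                       seed = derive_seed(seed, paste0("dose:", doses[i])))
    cv <- gen_growth_counts(p)
    cv$condition <- list(dose_uM = doses[i])
    cv
  })
  names(curves) <- as.character(doses)
  structure(curves, class = "dose_series",
            truth = list(hill_ic50 = hill_ic50, hill_slope = hill_slope,
                         doses = doses, rates = rates,
                         control_rate = growth$rate))
}
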