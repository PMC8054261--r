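#' Construct a dose-response curve of relative growth rates
#'
#' @param doses micromolar doses, strictly increasing and including 0.
#' @param rel_rates relative growth rates; the entry at dose 0 must be 1
#'   (the untreated anchor normalizes the curve).
#' @param condition optional named list identifying the condition.
#' @return an object of class `"dose_response_curve"`: a data.frame with
#'   columns `dose` and `rel_rate`.
#' @export
dose_response_curve <- function(doses, rel_rates, condition = list()) {
  stopifnot(is.numeric(doses), is.numeric(rel_rates),
            length(doses) == length(rel_rates))
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  if (!any(doses == 0)) stop("dose 0 must be present")
  if (abs(rel_rates[doses == 0] - 1) > 1e-8)
    stop("rel_rate at dose 0 must equal 1")
  out <- data.frame(dose = as.numeric(doses), rel_rate = as.numeric(rel_rates))
  structure(out, class = c("dose_response_curve", "data.frame"),
            condition = condition)
}

#' Assemble a dose-response curve from per-dose growth fits
#'
#' Computes the relative growth rate of every dose against the dose-0
#' control of the same condition/replicate and assembles the
#' dose-response curve.
#'
#' @param fits named list of [fit_exponential()] objects keyed by dose
#'   (names coercible to numeric); must include dose 0 with a positive
#'   fitted rate.
#' @return a [dose_response_curve()].
#' @export
build_curve <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  doses <- suppressWarnings(as.numeric(names(fits)))
  if (any(is.na(doses))) stop("fit list names must be numeric doses")
  o <- order(doses)
  doses <- doses[o]; fits <- fits[o]
  if (!any(doses == 0)) stop("missing untreated (dose 0) control fit")
  if (!any(doses > 0)) stop("need at least one positive dose besides the untreated control")
  ctrl <- fits[[which(doses == 0)]]
  rc <- if (inherits(ctrl, "growth_fit")) ctrl$rate_hat else as.numeric(ctrl)
  if (!is.finite(rc) || rc <= 0) stop("control (dose 0) rate must be > 0")
  rel <- vapply(fits, function(f) {
    r <- if (inherits(f, "growth_fit")) f$rate_hat else as.numeric(f)
    r / rc
  }, numeric(1))
  rel[doses == 0] <- 1
  dose_response_curve(doses, unname(rel))
}

#' Average replicate dose-response curves
#'
#' Pointwise mean of the relative rates across replicate curves sharing a
#' dose grid; the alternative to estimating a per-replicate IC50 and
#' averaging afterwards.
#'
#' @param curves list of [dose_response_curve()] objects with identical
#'   dose grids.
#' @return a [dose_response_curve()] of mean relative rates.
#' @export
average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  d0 <- curves[[1]]$dose
  for (cv in curves)
    if (!isTRUE(all.equal(cv$dose, d0))) stop("curves have differing dose grids")
  m <- rowMeans(vapply(curves, function(cv) cv$rel_rate, numeric(length(d0))))
  m[d0 == 0] <- 1
  dose_response_curve(d0, m)
}

#' IC50 by linear interpolation on a log-concentration scale
#'
#' Estimates the drug concentration at which the relative growth rate
#' falls to 50% of the untreated value.  Positive doses are scanned in
#' increasing order for the first adjacent pair bracketing 0.5; the IC50
#' is then read off by linear interpolation of relative rate against
#' log10(dose).  Dose 0 only anchors the normalization and is excluded
#' from the log axis.  An exact 0.5 at a dose returns that dose.  Curves
#' that never fall to 0.5 are censored `above_max`; curves already below
#' 0.5 at the lowest positive dose are censored `below_min`.  Negative
#' relative rates participate unchanged (they lie below 0.5).
#'
#' @param curve a [dose_response_curve()] with >= 2 positive doses.
#' @return an object of class `"ic50_estimate"`: list with `value` (uM or
#'   `NA` when censored), `censored` (`"none"`, `"above_max"`,
#'   `"below_min"`) and `bracket` (the two doses used, or `NULL`).
#' @examples
#' cv <- dose_response_curve(c(0, 0.185, 0.555), c(1, 0.6, 0.4))
#' ic50_log_interp(cv)$value # sqrt(0.185 * 0.555)
#' @export
ic50_log_interp <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  pos <- curve$dose > 0
  d <- curve$dose[pos]; rel <- curve$rel_rate[pos]
  if (length(d) < 2L) stop("need >= 2 positive doses")
  est <- function(value, censored, bracket = NULL) {
    structure(list(value = value, censored = censored, bracket = bracket),
              class = "ic50_estimate")
  }
  if (rel[1] < 0.5) return(est(NA_real_, "below_min"))
  if (rel[1] == 0.5) return(est(d[1], "none", c(d[1], d[1])))
  for (i in seq_len(length(d) - 1L)) {
    a <- rel[i]; b <- rel[i + 1L]
    if (a >= 0.5 && b <= 0.5) {
      if (a == 0.5) return(est(d[i], "none", c(d[i], d[i])))
      if (b == 0.5) return(est(d[i + 1L], "none", c(d[i + 1L], d[i + 1L])))
      lg <- log10(d[i]) + (a - 0.5) / (a - b) * (log10(d[i + 1L]) - log10(d[i]))
      return(est(10^lg, "none", c(d[i], d[i + 1L])))
    }
  }
  est(NA_real_, "above_max")
}

#' @export
print.ic50_estimate <- function(x, ...) {
  if (x$censored == "none")
    cat(sprintf("IC50 = %.4g uM (bracket %.4g-%.4g uM)\n",
                x$value, x$bracket[1], x$bracket[2]))
  else cat("IC50 censored:", x$censored, "\n")
  invisible(x)
}
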