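#' Configuration of the exponential growth fit
#'
#' @param max_iter maximum damped Gauss-Newton iterations (>= 1).
#' @param tol convergence tolerance on the relative parameter change (> 0).
#' @param lambda0 initial damping factor of the Levenberg-Marquardt
#'   iteration.
#' @param log_fallback if `TRUE` (default) curves containing zero counts
#'   fall back to initialization from `log(max(count, 1))`; the nonlinear
#'   fit itself always runs on raw counts.
#' @return an object of class `"fit_config"`.
#' @export
fit_config <- function(max_iter = 500L, tol = 1e-8, lambda0 = 1e-3,
                       log_fallback = TRUE) {
  stopifnot(max_iter >= 1L, tol > 0, lambda0 > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 lambda0 = lambda0, log_fallback = isTRUE(log_fallback)),
            class = "fit_config")
}

#' Fit an exponential growth model to live-cell counts
#'
#' Estimates `(n0, r)` of the exponential model `N(t) = n0 * exp(r * t)`
#' by unweighted nonlinear least squares on the raw counts, using a damped
#' (Levenberg-Marquardt) Gauss-Newton iteration.  Initialization takes
#' `n0` from the count at the earliest time (floored at 1) and `r` from
#' the ordinary least-squares slope of `log(max(count, 1))` against time.
#' Rates are unconstrained in sign: drug-treated populations may shrink.
#'
#' The damping factor decreases tenfold after an accepted step and
#' increases tenfold after a rejected one; iteration stops when the
#' relative parameter change drops below `config$tol` or after
#' `config$max_iter` iterations, and the convergence flag reports which.
#'
#' @param curve a [growth_curve()], or anything with numeric `times` and
#'   `counts` elements; >= 3 timepoints, counts not all zero.
#' @param config a [fit_config()] object.
#' @return an object of class `"growth_fit"`: list with `n0_hat`,
#'   `rate_hat`, `rate_se`, `n0_se`, `rss`, `converged`, `n_iter`, the
#'   parameter covariance `cov`, and the data.
#' @examples
#' gc <- gen_growth_counts(growth_params(n0 = 100, rate = 0.03, noise_cv = 0))
#' fit <- fit_exponential(gc)
#' coef(fit)
#' @export
fit_exponential <- function(curve, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  t <- as.numeric(curve$times); y <- as.numeric(curve$counts)
  if (length(t) < 3L) stop("need >= 3 timepoints to fit")
  if (any(!is.finite(t)) || any(!is.finite(y))) stop("non-finite inputs")
  if (all(y == 0)) stop("all counts are zero; nothing to fit")
  check_strictly_increasing(t)
  if (max(t) - min(t) <= 0) stop("times must span a positive interval")

  # initialization: n0 from earliest count, r from log-linear OLS slope
  n0 <- max(y[which.min(t)], 1)
  r <- unname(coef(lm(log(pmax(y, 1)) ~ t))[2])
  p <- c(n0, r)

  rss_of <- function(p) sum((y - p[1] * exp(p[2] * t))^2)
  rss <- rss_of(p)
  rss_init <- rss
  lambda <- config$lambda0
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < config$max_iter) {
    n_iter <- n_iter + 1L
    e <- exp(p[2] * t)
    res <- y - p[1] * e
    J <- cbind(e, p[1] * t * e) # model gradient wrt (n0, r)
    g <- crossprod(J, res)
    H <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:50) { # inner damping loop
      A <- H + lambda * diag(diag(H), 2)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(delta)) {
        p_new <- p + as.numeric(delta)
        rss_new <- rss_of(p_new)
        if (is.finite(rss_new) && rss_new <= rss) {
          step_ok <- TRUE
          lambda <- max(lambda / 10, 1e-12)
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok) { converged <- TRUE; break } # stuck at a (local) minimum
    rel <- max(abs(p_new - p) / pmax(abs(p), 1e-12))
    p <- p_new; rss <- rss_new
    if (rel < config$tol) { converged <- TRUE; break }
  }

  # covariance from the Gauss-Newton approximation at the optimum, under
  # the relative-error variance model var(y_i) = c^2 * mu_i^2 that count
  # noise in confluent imaging follows (error scales with the count)
  e <- exp(p[2] * t)
  mu <- pmax(p[1] * e, 1) # floor: relative error below one cell is meaningless
  J <- cbind(e, p[1] * t * e)
  dof <- length(y) - 2L
  c2 <- if (dof > 0) sum(((y - p[1] * e) / mu)^2) / dof else NA_real_
  cov <- tryCatch({
    B <- solve(crossprod(J))
    B %*% crossprod(J * sqrt(c2) * mu) %*% B
  }, error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(cov), 0))

  structure(list(n0_hat = p[1], rate_hat = p[2],
                 n0_se = se[1], rate_se = se[2],
                 rss = rss, rss_init = rss_init,
                 converged = converged, n_iter = n_iter, cov = cov,
                 times = t, counts = y,
                 condition = if (!is.null(curve$condition)) curve$condition else list()),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Exponential growth fit: N(t) = n0 * exp(r t)\n")
  cat(sprintf("  n0   = %.*g (se %.*g)\n", digits, x$n0_hat, digits, x$n0_se))
  cat(sprintf("  rate = %.*g /h (se %.*g)\n", digits, x$rate_hat, digits, x$rate_se))
  cat(sprintf("  rss = %.*g over %d timepoints; %s in %d iterations\n",
              digits, x$rss, length(x$times),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  dt <- log(2) / object$rate_hat
  out <- list(coef = cbind(estimate = c(n0 = object$n0_hat, rate = object$rate_hat),
                           se = c(object$n0_se, object$rate_se)),
              doubling_time_h = if (object$rate_hat > 0) dt else NA_real_,
              rss = object$rss, converged = object$converged,
              n_iter = object$n_iter, n = length(object$times))
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$coef)
  if (is.finite(x$doubling_time_h))
    cat(sprintf("doubling time: %.2f h\n", x$doubling_time_h))
  cat(sprintf("rss %.6g on %d points; converged: %s (%d iter)\n",
              x$rss, x$n, x$converged, x$n_iter))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(n0 = object$n0_hat, rate = object$rate_hat)
}

#' @export
predict.growth_fit <- function(object, times = object$times, ...) {
  object$n0_hat * exp(object$rate_hat * times)
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...) {
  object$counts - predict(object)
}

#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  s <- sqrt(object$rss / max(length(mu) - 2L, 1L))
  out <- replicate(nsim, pmax(round(mu + rnorm(length(mu), 0, s)), 0),
                   simplify = FALSE)
  data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.growth_fit <- function(x, ...) {
  plot(x$times, x$counts, xlab = "time (h)", ylab = "live cells",
       pch = 19, ...)
  tt <- seq(min(x$times), max(x$times), length.out = 100)
  lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Relative growth rate of a treated condition
#'
#' Ratio of the treated to the matched untreated growth rate; the
#' dimensionless response used on dose-response curves.  May be <= 0 when
#' a cytotoxic dose shrinks the population.
#'
#' @param treated,control [fit_exponential()] fits or bare numeric rates.
#' @return the ratio `treated / control`.  If the control rate is <= 0 the
#'   ratio is undefined: `NA` is returned with attribute
#'   `undefined_control = TRUE` and a warning.
#' @export
relative_growth_rate <- function(treated, control) {
  rt <- if (inherits(treated, "growth_fit")) treated$rate_hat else as.numeric(treated)
  rc <- if (inherits(control, "growth_fit")) control$rate_hat else as.numeric(control)
  if (!is.finite(rc) || rc <= 0) {
    warning("control growth rate is <= 0; relative rate undefined")
    return(structure(NA_real_, undefined_control = TRUE))
  }
  rt / rc
}
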