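# MCMC convergence diagnostics: split R-hat and a Geyer-style effective
# sample size, computed from a draws x chains matrix.

split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[(n - half + 1L):n, j])
  }))
  m <- ncol(halves); n2 <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n2 * var(means)
  if (!is.finite(W) || W <= 0) return(1) # degenerate (constant) chain
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

ess_mean <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  if (all(apply(mat, 2, sd) == 0)) return(n * m) # constant chains
  lag_max <- min(n - 1L, 250L)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    a <- acf(mat[, j], lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
    as.numeric(a)
  }, numeric(lag_max)))
  # Geyer initial positive sequence on paired sums
  s <- 0; k <- 1L
  while (k < length(rho)) {
    g <- rho[k] + rho[k + 1L]
    if (!is.finite(g) || g < 0) break
    s <- s + g
    k <- k + 2L
  }
  max(1, n * m / (1 + 2 * s))
}

# one adaptive random-walk Metropolis step on a scalar; returns the new
# value, the new log step size and whether the proposal was accepted.
# logpost_delta(delta) must return the log-posterior change.
rw_step <- function(value, log_step, logpost_delta, adapt, adapt_rate,
                    target = 0.44) {
  delta <- rnorm(1, 0, exp(log_step))
  lr <- logpost_delta(delta)
  alpha <- if (is.finite(lr)) min(1, exp(lr)) else 0
  accept <- runif(1) < alpha
  if (adapt) log_step <- log_step + adapt_rate * (alpha - target)
  list(value = if (accept) value + delta else value,
       log_step = log_step, accept = accept, delta = delta)
}

posterior_summary_row <- function(name, draws_mat) {
  x <- as.vector(draws_mat)
  data.frame(param = name, mean = mean(x),
             lower = unname(quantile(x, 0.025)),
             upper = unname(quantile(x, 0.975)),
             rhat = split_rhat(draws_mat), ess = ess_mean(draws_mat),
             stringsAsFactors = FALSE)
}
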