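#' Empirical-Bayes model of IC50 differences between oxygen conditions
#'
#' Models per-experiment IC50s on the log scale (the natural scale for a
#' fold change): within each cell line, `log(IC50)` has a cell-line
#' baseline plus, for every hypoxia level, an offset `delta` relative to
#' the normoxia reference.  `delta` carries a weakly informative Gaussian
#' prior and the residual SD a half-Cauchy prior, both scaled loosely to
#' the data.  The posterior of the fold change `exp(delta)` is reported
#' with its symmetric 95% credible interval.
#'
#' Sampling: the Gaussian-prior coefficients (baselines and deltas) admit
#' exact conjugate Gibbs draws; the log residual scale uses adaptive
#' random-walk Metropolis.  Convergence is gated on split R-hat < 1.05
#' and ESS > 400 for every reported delta.
#'
#' @param ic50_table data.frame with columns `ic50` (uM, > 0), `cell`
#'   (cell line) and `o2` (oxygen level, e.g. `"21%"`, `"1%"`, `"0.1%"`).
#'   Non-positive or missing IC50s (censored estimates) are excluded with
#'   a warning.
#' @param reference the `o2` level treated as normoxia baseline.
#' @param prior_scale_delta Gaussian prior SD for the log-IC50
#'   differences; `NULL` scales it to 10 times the SD of log IC50.
#' @param prior_scale_sigma half-Cauchy width for the residual SD;
#'   `NULL` for the same data-scaled default.
#' @param chains,iter,warmup,seed MCMC settings as in [hier_model_spec()].
#' @return an object of class `"ic50_diff_fit"`: list with `summary`
#'   (one row per cell line x hypoxia level: posterior mean and 95% CI of
#'   `delta` (log scale) and of the fold change, R-hat, ESS), `draws`,
#'   `converged`, `reference`.
#' @export
fit_ic50_difference_model <- function(ic50_table, reference = "21%",
                                      prior_scale_delta = NULL,
                                      prior_scale_sigma = NULL,
                                      chains = 2L, iter = 2500L,
                                      warmup = 500L, seed = 1L) {
  stopifnot(is.data.frame(ic50_table),
            all(c("ic50", "cell", "o2") %in% names(ic50_table)),
            chains >= 2L, iter > warmup)
  tab <- ic50_table
  bad <- !is.finite(tab$ic50) | tab$ic50 <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d non-positive/missing (censored) IC50 value(s)",
                    sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!reference %in% tab$o2)
    stop(sprintf("reference level '%s' absent from o2 column", reference))
  y <- log(tab$ic50)
  cellf <- as.factor(tab$cell)
  o2f <- factor(tab$o2, levels = c(reference, setdiff(unique(tab$o2), reference)))
  cnt <- table(cellf, o2f)
  if (any(cnt < 2L))
    stop("need >= 2 replicate IC50s per (cell line, O2) combination")
  C <- nlevels(cellf); L <- nlevels(o2f) # level 1 is the reference
  if (L < 2L) stop("need at least one hypoxia level besides the reference")
  ci <- as.integer(cellf); li <- as.integer(o2f)
  n <- length(y)

  sdy <- max(sd(y), 1e-3)
  wd <- prior_scale_delta %||% (10 * sdy)
  ws <- prior_scale_sigma %||% (10 * sdy)
  m0 <- mean(y); wa <- 10 * sdy # baseline prior, loosely centered on the data

  keep <- iter - warmup
  dnames <- as.vector(outer(levels(cellf), levels(o2f)[-1],
                            function(a, b) paste0(a, "|", b)))
  draws <- c(lapply(dnames, function(x) matrix(NA_real_, keep, chains)),
             list(matrix(NA_real_, keep, chains)))
  names(draws) <- c(dnames, "sigma")
  idx_cell <- lapply(seq_len(C), function(cc) which(ci == cc))
  idx_cl <- lapply(seq_len(C), function(cc)
    lapply(seq_len(L), function(l) which(ci == cc & li == l)))

  for (ch in seq_len(chains)) {
    with_substream(seed, paste0("ic50_chain", ch), {
      alpha <- vapply(seq_len(C), function(cc)
        mean(y[idx_cl[[cc]][[1]]]), numeric(1)) + rnorm(C, 0, 0.1 * sdy)
      delta <- matrix(0, C, L) # column 1 stays 0 (reference)
      lsig <- log(sdy) + rnorm(1, 0, 0.3)
      ls_step <- log(0.5)
      for (it in seq_len(iter)) {
        s2inv <- exp(-2 * lsig)
        # baselines: conjugate Gaussian
        for (cc in seq_len(C)) {
          A <- idx_cell[[cc]]
          r <- y[A] - delta[cc, li[A]]
          prec <- length(A) * s2inv + 1 / wa^2
          alpha[cc] <- rnorm(1, (sum(r) * s2inv + m0 / wa^2) / prec,
                             sqrt(1 / prec))
        }
        # hypoxia offsets: conjugate Gaussian
        for (cc in seq_len(C)) for (l in 2:L) {
          A <- idx_cl[[cc]][[l]]
          if (!length(A)) next
          r <- y[A] - alpha[cc]
          prec <- length(A) * s2inv + 1 / wd^2
          delta[cc, l] <- rnorm(1, sum(r) * s2inv / prec, sqrt(1 / prec))
        }
        # residual scale: adaptive log RW-MH with half-Cauchy prior
        res <- y - alpha[ci] - delta[cbind(ci, li)]
        step <- rnorm(1, 0, exp(ls_step))
        lnew <- lsig + step
        ssq <- sum(res^2)
        dll <- -n * step - 0.5 * ssq * (exp(-2 * lnew) - exp(-2 * lsig))
        dlp <- dcauchy(exp(lnew), 0, ws, log = TRUE) -
               dcauchy(exp(lsig), 0, ws, log = TRUE) + step
        alpha_mh <- min(1, exp(dll + dlp))
        if (runif(1) < alpha_mh) lsig <- lnew
        if (it <= warmup) ls_step <- ls_step + it^-0.6 * (alpha_mh - 0.44)

        if (it > warmup) {
          k <- it - warmup
          for (cc in seq_len(C)) for (l in 2:L)
            draws[[paste0(levels(cellf)[cc], "|", levels(o2f)[l])]][k, ch] <-
              delta[cc, l]
          draws[["sigma"]][k, ch] <- exp(lsig)
        }
      }
    })
  }

  rows <- lapply(dnames, function(nm) {
    d <- draws[[nm]]
    fc <- exp(d)
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    data.frame(cell = parts[1], o2 = parts[2],
               delta_mean = mean(d),
               delta_lower = unname(quantile(d, 0.025)),
               delta_upper = unname(quantile(d, 0.975)),
               fold_mean = mean(fc),
               fold_lower = unname(quantile(fc, 0.025)),
               fold_upper = unname(quantile(fc, 0.975)),
               rhat = split_rhat(d), ess = ess_mean(d),
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, rows)
  converged <- all(is.finite(summ$rhat)) && all(summ$rhat < 1.05) &&
    all(summ$ess > 400)
  if (!converged)
    warning("IC50-difference sampler flagged non-convergence")
  structure(list(summary = summ, draws = draws, converged = converged,
                 reference = reference),
            class = "ic50_diff_fit")
}

#' @export
print.ic50_diff_fit <- function(x, digits = 3, ...) {
  cat(sprintf("IC50 differences vs %s (log-scale model, %s)\n", x$reference,
              if (x$converged) "converged" else "NOT converged"))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s @ %s O2: fold change %.*g (95%% CI %.*g-%.*g)\n",
                s$cell[i], s$o2[i], digits, s$fold_mean[i],
                digits, s$fold_lower[i], digits, s$fold_upper[i]))
  invisible(x)
}

#' @export
summary.ic50_diff_fit <- function(object, ...) object$summary
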