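#' Exact two-sided sign test
#'
#' Tests whether paired differences trend in a single direction, using
#' only their signs: under the null the number of positive signs among
#' the `n` non-tied pairs is Binomial(n, 1/2).  The two-sided p-value is
#' the doubled smaller exact tail, capped at 1.  Because only the order
#' of the paired conditions enters, the test is insensitive to
#' cross-experiment measurement variation -- the reason it suits
#' growth-rate comparisons across oxygen levels pooled over experiments.
#'
#' @param deltas numeric vector of signed differences; zeros (ties) are
#'   dropped.
#' @return an object of class `"sign_test"`: list with `n` (non-tied
#'   pairs), `k` (positive differences), `p_two_sided`.
#' @examples
#' sign_test_two_sided(rep(-1, 8))$p_two_sided # 2 * (1/2)^8 = 0.0078125
#' @export
sign_test_two_sided <- function(deltas) {
  stopifnot(is.numeric(deltas))
  deltas <- deltas[is.finite(deltas)]
  s <- sign(deltas)
  s <- s[s != 0]
  n <- length(s)
  if (n == 0L) stop("all differences are ties; sign test undefined")
  k <- sum(s > 0)
  # exact tail sums of Binomial(n, 1/2)
  lower <- sum(dbinom(0:k, n, 0.5))
  upper <- sum(dbinom(k:n, n, 0.5))
  p <- min(1, 2 * min(lower, upper))
  structure(list(n = n, k = k, p_two_sided = p), class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf("Exact two-sided sign test: %d of %d differences positive, P = %.3f\n",
              x$k, x$n, x$p_two_sided))
  invisible(x)
}

#' Two-sided Welch t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value from the t distribution, as used
#' for pairwise growth-rate comparisons.  The computation is delegated to
#' [stats::t.test()] with `var.equal = FALSE`.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values and
#'   nonzero variance.
#' @return an object of class `"welch_test"`: list with `t`, `df`,
#'   `p_two_sided`, and the group means.
#' @export
welch_t_test <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 values")
  if (var(group_a) == 0 && var(group_b) == 0)
    stop("degenerate variance: both groups are constant")
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sided t-test: t = %.4g, df = %.3g, P = %.4g\n",
              x$t, x$df, x$p_two_sided))
  invisible(x)
}
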