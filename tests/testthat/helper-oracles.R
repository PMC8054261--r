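# Independent oracles used across the suite.

# brute-force local population SD with mirror (reflect-including-edge)
# padding; nested loops, no shared code with the implementation
brute_force_local_sd <- function(m, k) {
  p <- (k - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(p:1, 1:nr, nr:(nr - p + 1))
  cidx <- c(p:1, 1:nc, nc:(nc - p + 1))
  mp <- m[ridx, cidx]
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    w <- mp[i:(i + k - 1), j:(j + k - 1)]
    out[i, j] <- sqrt(mean((w - mean(w))^2)) # population SD
  }
  out
}

# exact two-sided sign-test p by enumerating all 2^n equiprobable patterns
enum_sign_test_p <- function(n, k) {
  cnt_le <- 0; cnt_ge <- 0
  for (pat in 0:(2^n - 1)) {
    kk <- sum(bitwAnd(bitwShiftR(pat, 0:(n - 1)), 1L))
    if (kk <= k) cnt_le <- cnt_le + 1
    if (kk >= k) cnt_ge <- cnt_ge + 1
  }
  min(1, 2 * min(cnt_le, cnt_ge) / 2^n)
}

# Welch statistic, Welch-Satterthwaite df and p, from the textbook formulas
welch_by_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

# rasterized filled circle mask
circle_mask <- function(n, r, cy = n / 2, cx = n / 2) {
  m <- matrix(FALSE, n, n)
  (row(m) - cy)^2 + (col(m) - cx)^2 <= r^2
}

# small fast scene for unit tests (unit tests don't need the full-size well)
tiny_scene_params <- function(seed, n_cells_on = 30L, n_cells_off = 12L, ...) {
  disc_scene_params(image_shape = c(192L, 192L), pixel_size = 36,
                    n_cells_on = n_cells_on, n_cells_off = n_cells_off,
                    seed = seed, ...)
}

stiffness_contrast <- list(stiff = list(factor = "plate",
                                        a = "softwell_2kPa",
                                        b = "softwell_0.2kPa"))
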