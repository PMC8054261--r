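#' Parameters for a synthetic disc well scene
#'
#' Describes one simulated well scan containing an ECM scaffold disc:
#' image geometry, disc placement, the intensity model and the cell-spot
#' layout.  Physical discs are 6 mm in diameter; the default pixel size of
#' 18 um/px puts the 3 mm disc radius at ~167 px inside a 384 x 384 field.
#' Intensities are on an arbitrary 16-bit-like scale.
#'
#' The intensity model is: a radially symmetric quadratic vignette (the
#' light profile), plus a uniform additive offset on the disc, plus
#' zero-mean Gaussian texture whose SD is larger on-disc than off-disc
#' (the premise the segmentation exploits), plus Gaussian nuclear spots at
#' each cell centroid, plus Gaussian camera noise.
#'
#' @param image_shape integer (rows, cols) in pixels.
#' @param pixel_size um per pixel.
#' @param disc_center (row, col) of the disc center, 0-based pixels;
#'   default image center.
#' @param disc_radius disc radius in pixels; default 3000 um / pixel_size.
#' @param disc_offset additive intensity of the disc material.
#' @param texture_sd_on,texture_sd_off SD of the Gaussian texture inside /
#'   outside the disc; must satisfy `texture_sd_on >= texture_sd_off`
#'   (equality is allowed but flagged as a degenerate no-contrast scene).
#' @param illum_base,illum_amplitude light-profile plateau intensity and
#'   fractional corner fall-off of the quadratic vignette.
#' @param n_cells_on,n_cells_off number of cell spots on / off the disc.
#' @param spot_amplitude,spot_sigma peak intensity and SD (px) of each
#'   Gaussian nuclear spot.
#' @param dead_fraction fraction of cells labelled dead (propidium-iodide
#'   positive) in the detection table.
#' @param camera_sd SD of additive Gaussian camera noise.
#' @param allow_clipped if `FALSE` (default) the disc must lie fully
#'   inside the image.
#' @param seed integer RNG seed.
#' @return an object of class `"disc_scene_params"`.
#' @export
disc_scene_params <- function(image_shape = c(384L, 384L), pixel_size = 18,
                              disc_center = (image_shape - 1) / 2,
                              disc_radius = 3000 / pixel_size,
                              disc_offset = 200,
                              texture_sd_on = 80, texture_sd_off = 15,
                              illum_base = 1000, illum_amplitude = 0.15,
                              n_cells_on = 50, n_cells_off = 20,
                              spot_amplitude = 400, spot_sigma = 2,
                              dead_fraction = 0.1, camera_sd = 4,
                              allow_clipped = FALSE, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            length(disc_center) == 2L, disc_radius > 0, pixel_size > 0,
            texture_sd_on >= 0, texture_sd_off >= 0, camera_sd >= 0,
            n_cells_on >= 0, n_cells_off >= 0, spot_sigma > 0,
            dead_fraction >= 0, dead_fraction <= 1)
  if (texture_sd_on < texture_sd_off)
    stop("texture_sd_on must be >= texture_sd_off (on-disc texture is the stronger one)")
  if (!allow_clipped) {
    lo <- disc_center - disc_radius
    hi <- disc_center + disc_radius
    if (any(lo < 0) || any(hi > image_shape - 1))
      stop("disc extends outside the image; set allow_clipped = TRUE to permit this")
  }
  structure(list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 disc_center = as.numeric(disc_center),
                 disc_radius = disc_radius, disc_offset = disc_offset,
                 texture_sd_on = texture_sd_on, texture_sd_off = texture_sd_off,
                 illum_base = illum_base, illum_amplitude = illum_amplitude,
                 n_cells_on = as.integer(n_cells_on),
                 n_cells_off = as.integer(n_cells_off),
                 spot_amplitude = spot_amplitude, spot_sigma = spot_sigma,
                 dead_fraction = dead_fraction, camera_sd = camera_sd,
                 allow_clipped = allow_clipped, seed = as.integer(seed)),
            class = "disc_scene_params")
}

#' Generate a synthetic well scene with ground truth
#'
#' Renders the scene described by a [disc_scene_params()] object and
#' returns the image, the matching empty-well light profile, the exact
#' rasterized disc mask, and a detection table in which every centroid
#' carries its true on/off-disc label and a live/dead viability call.
#'
#' Cell centroids are placed uniformly at random in their region (on-disc
#' cells uniform over the disc, off-disc cells uniform over the
#' complement) and contribute a Gaussian intensity spot.
#'
#' @param params a [disc_scene_params()] object.
#' @param time_h time stamp (hours) written into the detection table.
#' @param well well identifier written into the detection table.
#' @return an object of class `"well_scene"`: list with elements `image`
#'   and `profile` (numeric matrices), `mask` (logical matrix, ground
#'   truth), `cells` (data.frame: well, time_h, x_px, y_px, viability,
#'   on_disc; x = column and y = row, 0-based), `params`, and `meta`
#'   (flags, e.g. `no_texture_contrast`).
#' @export
gen_well_scene <- function(params, time_h = 0, well = "A1") {
  stopifnot(inherits(params, "disc_scene_params"))
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  area_px <- pi * params$disc_radius^2
  cap_on <- max(1, floor(area_px / 4))
  cap_off <- max(1, floor((nr * nc - area_px) / 4))
  if (params$n_cells_on > cap_on)
    stop(sprintf("n_cells_on = %d exceeds on-disc area capacity (%d)",
                 params$n_cells_on, cap_on))
  if (params$n_cells_off > cap_off)
    stop(sprintf("n_cells_off = %d exceeds off-disc area capacity (%d)",
                 params$n_cells_off, cap_off))

  rows0 <- matrix(0:(nr - 1), nr, nc)        # y coordinate of each pixel
  cols0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  d2 <- (rows0 - params$disc_center[1])^2 + (cols0 - params$disc_center[2])^2
  mask <- d2 <= params$disc_radius^2
  profile <- light_profile(params)

  scene <- with_substream(params$seed, "scene", {
    img <- profile + params$disc_offset * mask
    img <- img + ifelse(mask,
                        rnorm(nr * nc, 0, params$texture_sd_on),
                        rnorm(nr * nc, 0, params$texture_sd_off))
    on_xy <- sample_in_disc(params$n_cells_on, params$disc_center,
                            params$disc_radius, nr, nc)
    off_xy <- sample_off_disc(params$n_cells_off, params$disc_center,
                              params$disc_radius, nr, nc)
    cells <- rbind(on_xy, off_xy)
    on_flag <- rep(c(TRUE, FALSE), c(nrow(on_xy), nrow(off_xy)))
    for (i in seq_len(nrow(cells)))
      img <- add_spot(img, cells[i, 1], cells[i, 2],
                      params$spot_amplitude, params$spot_sigma)
    if (params$camera_sd > 0)
      img <- img + rnorm(nr * nc, 0, params$camera_sd)
    n_cells <- nrow(cells)
    dead <- rep(FALSE, n_cells)
    if (params$dead_fraction > 0 && n_cells > 0)
      dead <- runif(n_cells) < params$dead_fraction
    list(img = img, cells = cells, on_flag = on_flag, dead = dead)
  })

  cells <- data.frame(
    well = rep(well, length(scene$on_flag)),
    time_h = rep(time_h, length(scene$on_flag)),
    x_px = if (length(scene$on_flag)) scene$cells[, 2] else numeric(0),
    y_px = if (length(scene$on_flag)) scene$cells[, 1] else numeric(0),
    viability = ifelse(scene$dead, "dead", "live"),
    on_disc = scene$on_flag,
    stringsAsFactors = FALSE)

  structure(list(image = scene$img, profile = profile, mask = mask,
                 cells = cells, params = params,
                 meta = list(no_texture_contrast =
                               params$texture_sd_on == params$texture_sd_off)),
            class = "well_scene")
}

# radially symmetric quadratic vignette, normalized to the image diagonal
light_profile <- function(params) {
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  rows0 <- matrix(0:(nr - 1), nr, nc)
  cols0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  d2 <- (rows0 - cy)^2 + (cols0 - cx)^2
  dmax2 <- cy^2 + cx^2
  params$illum_base * (1 - params$illum_amplitude * d2 / dmax2)
}

# n uniform points in the disc (polar with sqrt radius), clipped to image
sample_in_disc <- function(n, center, radius, nr, nc) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  y <- pmin(pmax(center[1] + r * sin(th), 0), nr - 1)
  x <- pmin(pmax(center[2] + r * cos(th), 0), nc - 1)
  cbind(y, x)
}

# n uniform points in the image outside the disc, by rejection
sample_off_disc <- function(n, center, radius, nr, nc) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 4 * (n - nrow(out)) + 16
    y <- runif(m, 0, nr - 1); x <- runif(m, 0, nc - 1)
    keep <- (y - center[1])^2 + (x - center[2])^2 > radius^2
    out <- rbind(out, cbind(y, x)[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# add a Gaussian spot at (y, x) within a +-4 sigma window
add_spot <- function(img, y, x, amplitude, sigma) {
  w <- ceiling(4 * sigma)
  r0 <- max(0, floor(y) - w); r1 <- min(nrow(img) - 1, floor(y) + w)
  c0 <- max(0, floor(x) - w); c1 <- min(ncol(img) - 1, floor(x) + w)
  rr <- r0:r1; cc <- c0:c1
  g <- exp(-outer((rr - y)^2, (cc - x)^2, "+") / (2 * sigma^2))
  img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + amplitude * g
  img
}
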