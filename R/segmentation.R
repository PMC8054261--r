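#' Parameters controlling disc segmentation
#'
#' The three swept parameters of the disc-segmentation procedure (texture
#' kernel, candidate threshold, structuring-element size) plus the median
#' kernel and the threshold on the filtered texture response.
#'
#' @param std_kernel odd window size (px) of the local standard-deviation
#'   filter; >= 3.
#' @param median_kernel odd window size (px) of the median filter applied
#'   to the texture response; >= 3.
#' @param texture_threshold threshold on the median-filtered local-SD
#'   response above which a pixel belongs to the texture core (> 0, image
#'   intensity units).
#' @param candidate_threshold absolute intensity deviation from the
#'   light profile above which a pixel becomes an on-disc candidate (> 0).
#' @param struct_size radius (px) of the disk structuring element used by
#'   the morphological refinement; >= 1.
#' @param illum_correct if `TRUE` the texture filter runs on
#'   profile-subtracted intensities; default `FALSE` (raw image).
#' @return an object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(std_kernel = 9L, median_kernel = 5L,
                                texture_threshold = 40,
                                candidate_threshold = 100,
                                struct_size = 8L, illum_correct = FALSE) {
  std_kernel <- as.integer(std_kernel); median_kernel <- as.integer(median_kernel)
  if (std_kernel < 3L || std_kernel %% 2L == 0L)
    stop("std_kernel must be odd and >= 3")
  if (median_kernel < 3L || median_kernel %% 2L == 0L)
    stop("median_kernel must be odd and >= 3")
  if (texture_threshold <= 0) stop("texture_threshold must be > 0")
  if (candidate_threshold <= 0) stop("candidate_threshold must be > 0")
  if (struct_size < 1) stop("struct_size must be >= 1")
  structure(list(std_kernel = std_kernel, median_kernel = median_kernel,
                 texture_threshold = texture_threshold,
                 candidate_threshold = candidate_threshold,
                 struct_size = as.integer(struct_size),
                 illum_correct = isTRUE(illum_correct)),
            class = "segmentation_params")
}

# reflect-pad a matrix by p pixels on every side (mirror including edge)
reflect_pad <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  if (p == 0) return(m)
  if (p >= nr || p >= nc) stop("padding exceeds image size")
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ri, ci]
}

# k x k box sums via an integral image (exact, O(n))
box_sum <- function(m, k) {
  p <- (k - 1L) %/% 2L
  mp <- reflect_pad(m, p)
  S <- apply(apply(mp, 2, cumsum), 1, cumsum) # S[j, i] after t(); transpose back
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  nr <- nrow(m); nc <- ncol(m)
  i1 <- 1:nr; i2 <- i1 + k - 1L
  j1 <- 1:nc; j2 <- j1 + k - 1L
  S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
    S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
}

#' Local standard-deviation texture filter
#'
#' Replaces each pixel by the population standard deviation of its
#' `kernel` x `kernel` neighborhood, with mirror (reflection) padding at
#' the borders.  ECM material has markedly higher local intensity
#' variance than the empty well bottom, so this response is the primary
#' evidence for the disc region.
#'
#' @param image numeric matrix.
#' @param kernel odd window size in pixels, >= 3 and at most the smaller
#'   image dimension.
#' @return numeric matrix of the same shape, nonnegative everywhere.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 9
#' local_std_filter(m, 3)[5, 5] # sd of {0 x 8, 9} = sqrt(8)
#' @export
local_std_filter <- function(image, kernel) {
  stopifnot(is.matrix(image), is.numeric(image))
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  if (kernel < 3L) stop("kernel must be >= 3")
  if (kernel > min(dim(image))) stop("kernel exceeds image dimensions")
  n <- as.numeric(kernel)^2
  m1 <- box_sum(image, kernel) / n
  m2 <- box_sum(image^2, kernel) / n
  v <- pmax(m2 - m1^2, 0)
  sqrt(v)
}

#' Candidate on-disc pixels from the light profile
#'
#' Flags pixels whose intensity deviates from the empty-well light
#' profile by more than `threshold`.  The disc material both scatters and
#' absorbs, so on-disc pixels depart from the illumination reference in
#' either direction; off-disc pixels track it closely.
#'
#' @param image,profile numeric matrices of identical shape.
#' @param threshold intensity deviation threshold (> 0).
#' @return logical matrix: `TRUE` where `|image - profile| > threshold`.
#' @export
candidate_pixels <- function(image, profile, threshold) {
  stopifnot(is.matrix(image), is.matrix(profile))
  if (!all(dim(image) == dim(profile)))
    stop(sprintf("image (%dx%d) and profile (%dx%d) shapes differ",
                 nrow(image), ncol(image), nrow(profile), ncol(profile)))
  if (threshold <= 0) stop("threshold must be > 0")
  abs(image - profile) > threshold
}

#' Construct a disc mask object
#'
#' @param mask logical matrix (disc foreground).
#' @param params the [segmentation_params()] that produced it, or `NULL`.
#' @param no_disc flag set when no disc was found (mask then empty).
#' @param score selection score assigned by [sweep_segmentation()].
#' @return an object of class `"disc_mask"`.
#' @export
disc_mask <- function(mask, params = NULL, no_disc = FALSE, score = NA_real_) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, params = params, no_disc = isTRUE(no_disc),
                 score = score),
            class = "disc_mask")
}

#' @export
print.disc_mask <- function(x, ...) {
  if (x$no_disc) cat("Disc mask: no disc found\n")
  else cat(sprintf("Disc mask: %d px foreground (%.1f%% of %d x %d image)\n",
                   sum(x$mask), 100 * mean(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Morphological refinement of a texture core with profile candidates
#'
#' Combines the thresholded texture core with the light-profile candidate
#' pixels and cleans the result: (1) union of core and candidates;
#' (2) dilation with a disk structuring element; (3) reconstruction from
#' the core as marker -- only connected components containing core pixels
#' survive; (4) hole filling; (5) erosion with the same disk to undo the
#' dilation bias; (6) retention of the largest connected component.
#'
#' @param core logical matrix, thresholded texture response (the marker).
#' @param candidates logical matrix, same shape (from [candidate_pixels()]).
#' @param struct_size disk structuring-element radius in pixels.
#' @return a [disc_mask()]; an empty core yields an empty mask flagged
#'   `no_disc` rather than an error.
#' @export
morph_refine <- function(core, candidates, struct_size) {
  stopifnot(is.matrix(core), is.matrix(candidates))
  if (!all(dim(core) == dim(candidates))) stop("core and candidates shapes differ")
  core <- core > 0; candidates <- candidates > 0
  if (!any(core))
    return(disc_mask(matrix(FALSE, nrow(core), ncol(core)), no_disc = TRUE))
  kern <- EBImage::makeBrush(2L * as.integer(struct_size) + 1L, shape = "disc")
  m <- core | candidates
  m <- EBImage::dilate(m * 1, kern) > 0
  lab <- EBImage::bwlabel(m)
  keep <- unique(lab[core & lab > 0])
  m <- matrix(lab %in% keep & lab > 0, nrow(lab), ncol(lab))
  m <- EBImage::fillHull(m * 1) > 0
  m <- EBImage::erode(m * 1, kern) > 0
  m <- largest_component(m)
  if (!any(m)) return(disc_mask(m, no_disc = TRUE))
  disc_mask(m)
}

largest_component <- function(m) {
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m * 1)
  tab <- tabulate(lab[lab > 0])
  matrix(lab == which.max(tab), nrow(m), ncol(m))
}

#' Segment the ECM disc in a well image
#'
#' Full disc-segmentation procedure: a local standard-deviation filter
#' followed by a median filter finds the main textured structure of the
#' disc; comparison with the empty-well light profile adds candidate
#' on-disc pixels; morphological refinement ([morph_refine()]) merges and
#' cleans them.
#'
#' @param image numeric matrix, the well scan.
#' @param profile numeric matrix, the empty-well light profile (same shape).
#' @param params a [segmentation_params()] object.
#' @return a [disc_mask()] carrying `params` as provenance.
#' @seealso [sweep_segmentation()] for the parameter sweep and automated
#'   selection.
#' @export
segment_disc <- function(image, profile, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  if (!all(dim(image) == dim(profile))) stop("image and profile shapes differ")
  base <- if (params$illum_correct) image - profile else image
  resp <- local_std_filter(base, params$std_kernel)
  resp <- median_filter(resp, params$median_kernel)
  core <- resp > params$texture_threshold
  cand <- candidate_pixels(image, profile, params$candidate_threshold)
  out <- morph_refine(core, cand, params$struct_size)
  out$params <- params
  out
}

# median filter with an odd window; EBImage's constant-time filter works on
# [0, 1] data, so rescale through it and back
median_filter <- function(m, kernel) {
  half <- (as.integer(kernel) - 1L) %/% 2L
  rng <- range(m)
  if (rng[2] <= rng[1]) return(m)
  scaled <- (m - rng[1]) / (rng[2] - rng[1])
  out <- EBImage::medianFilter(scaled, half)
  as.matrix(out) * (rng[2] - rng[1]) + rng[1]
}

# area and isoperimetric circularity (clamped at 1) of a binary mask
mask_shape <- function(mask) {
  a <- sum(mask)
  if (a == 0) return(list(area = 0, perimeter = 0, circularity = 0))
  lab <- EBImage::bwlabel(mask * 1)
  fe <- EBImage::computeFeatures.shape(lab)
  per <- sum(fe[, "s.perimeter"])
  circ <- if (per > 0) min(1, 4 * pi * a / per^2) else 0
  list(area = a, perimeter = per, circularity = circ)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices or [disc_mask()] objects of equal shape.
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (inherits(a, "disc_mask")) a <- a$mask
  if (inherits(b, "disc_mask")) b <- b$mask
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Sweep segmentation parameters and select the best mask
#'
#' Runs [segment_disc()] for every parameter set in `grid` and scores each
#' resulting mask by how well it matches the known disc geometry:
#' `S = |area - expected_area| / expected_area +
#' circularity_weight * (1 - circularity)`, where circularity is the
#' isoperimetric ratio `4 * pi * area / perimeter^2` clamped at 1.  The
#' lowest score wins; ties break to the earlier grid entry.  The full
#' ranking is returned so a human can override the automated choice.
#'
#' @param image,profile numeric matrices as in [segment_disc()].
#' @param grid non-empty list of [segmentation_params()] objects.
#' @param expected_area expected disc area in px^2 (from the 6 mm disc
#'   diameter and the pixel size).
#' @param circularity_weight weight of the circularity penalty (>= 0).
#' @return list with `best` (a [disc_mask()] with its score filled in; a
#'   `no_disc` mask if every candidate was empty), `ranking` (data.frame:
#'   grid index, area, circularity, score, ordered best first) and
#'   `masks` (all candidate [disc_mask()]s in grid order).
#' @export
sweep_segmentation <- function(image, profile, grid, expected_area,
                               circularity_weight = 0.5) {
  stopifnot(is.list(grid), length(grid) >= 1L, expected_area > 0,
            circularity_weight >= 0)
  masks <- lapply(grid, function(p) segment_disc(image, profile, p))
  stats <- lapply(masks, function(mk) mask_shape(mk$mask))
  score <- vapply(seq_along(masks), function(i) {
    if (masks[[i]]$no_disc || stats[[i]]$area == 0) return(Inf)
    abs(stats[[i]]$area - expected_area) / expected_area +
      circularity_weight * (1 - stats[[i]]$circularity)
  }, numeric(1))
  ranking <- data.frame(grid_index = seq_along(grid),
                        area = vapply(stats, `[[`, numeric(1), "area"),
                        circularity = vapply(stats, `[[`, numeric(1), "circularity"),
                        score = score)
  ord <- order(ranking$score, ranking$grid_index) # stable: earlier entry wins ties
  ranking <- ranking[ord, ]
  if (!is.finite(ranking$score[1])) {
    best <- disc_mask(matrix(FALSE, nrow(image), ncol(image)), no_disc = TRUE)
  } else {
    best <- masks[[ranking$grid_index[1]]]
    best$score <- ranking$score[1]
  }
  list(best = best, ranking = ranking, masks = masks)
}

#' Default segmentation parameter grid
#'
#' A small grid over the three swept parameters (texture kernel size,
#' candidate threshold, structuring-element size) around the defaults.
#'
#' @param std_kernels,candidate_thresholds,struct_sizes vectors of values
#'   to cross.
#' @return list of [segmentation_params()].
#' @export
default_segmentation_grid <- function(std_kernels = c(7L, 9L, 11L),
                                      candidate_thresholds = c(60, 100, 140),
                                      struct_sizes = c(5L, 8L, 11L)) {
  g <- expand.grid(k = std_kernels, ct = candidate_thresholds,
                   s = struct_sizes)
  lapply(seq_len(nrow(g)), function(i) {
    segmentation_params(std_kernel = g$k[i], candidate_threshold = g$ct[i],
                        struct_size = g$s[i])
  })
}
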