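#' Write an intensity image as 16-bit TIFF
#'
#' Intensities are stored as 16-bit unsigned values; `scale` maps image
#' units to the \[0, 65535\] range (values are clipped).
#'
#' @param image numeric matrix.
#' @param path output file.
#' @param scale intensity corresponding to the 16-bit maximum.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = 65535) {
  stopifnot(is.matrix(image))
  m <- pmin(pmax(image / scale, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 16-bit TIFF intensity image
#'
#' @param path TIFF file written by [write_image_tiff()].
#' @param scale intensity corresponding to the 16-bit maximum.
#' @return numeric matrix.
#' @export
read_image_tiff <- function(path, scale = 65535) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * scale
}

#' Write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask logical matrix or [disc_mask()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "disc_mask")) mask <- mask$mask
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG file.
#' @return logical matrix (`TRUE` = foreground).
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write a cell-detection table as CSV
#'
#' Columns: `well`, `time_h`, `x_px`, `y_px`, `viability` (live/dead) and
#' any extra columns present (e.g. `on_disc`).  A header comment records
#' the coordinate convention: 0-based, x = column, y = row.
#'
#' @param cells data.frame of detections.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(cells, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cell centroids: 0-based pixel coordinates, x_px = column, y_px = row",
             con)
  write.csv(cells, con, row.names = FALSE)
  invisible(path)
}

#' Read a cell-detection table written by [write_detections_csv()]
#'
#' @param path CSV file (leading `#` comment lines are skipped).
#' @return data.frame of detections.
#' @export
read_detections_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write scene ground truth as a JSON sidecar
#'
#' @param scene a [gen_well_scene()] result.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_scene_truth_json <- function(scene, path) {
  stopifnot(inherits(scene, "well_scene"))
  p <- scene$params
  truth <- list(disc_center = p$disc_center, disc_radius = p$disc_radius,
                pixel_size_um = p$pixel_size,
                image_shape = p$image_shape,
                mask_area_px = sum(scene$mask),
                n_cells_on = sum(scene$cells$on_disc),
                n_cells_off = sum(!scene$cells$on_disc),
                seed = p$seed, meta = scene$meta)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
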