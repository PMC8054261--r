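#' Co-register cell centroids with a disc mask
#'
#' Overlays each detected cell center on the segmented disc mask and
#' labels it on-disc or off-disc.  Centroids are continuous 0-based
#' coordinates with `x_px` the column and `y_px` the row; the lookup pixel
#' is obtained by rounding each coordinate half-up (a single deterministic
#' rule so boundary cells are classified reproducibly).
#'
#' @param cells data.frame with columns `x_px`, `y_px` (0-based
#'   continuous centroids) and optionally `well`, `time_h`, `viability`.
#' @param mask a [disc_mask()] or logical matrix aligned to the image the
#'   centroids were measured in.
#' @return the input data.frame with an `on_disc` logical column, class
#'   `"registered_cells"`.  The on/off partition is exhaustive and
#'   exclusive: every row is labelled.
#' @export
register_cells <- function(cells, mask) {
  if (inherits(mask, "disc_mask")) mask <- mask$mask
  stopifnot(is.data.frame(cells), is.matrix(mask), is.logical(mask))
  req <- c("x_px", "y_px")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("cells is missing column(s): ", paste(miss, collapse = ", "))
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- floor(cells$y_px + 0.5) + 1L # round half up, then 1-based row
  ci <- floor(cells$x_px + 0.5) + 1L
  bad <- which(ri < 1L | ri > nr | ci < 1L | ci > nc |
                 !is.finite(cells$x_px) | !is.finite(cells$y_px))
  if (length(bad))
    stop(sprintf("centroid(s) out of image bounds at row index %s",
                 paste(head(bad, 5L), collapse = ", ")))
  out <- cells
  out$on_disc <- if (nrow(cells)) mask[cbind(ri, ci)] else logical(0)
  class(out) <- c("registered_cells", "data.frame")
  out
}

#' Per-timepoint registration summary
#'
#' Tallies live/dead and on/off-disc detections at each timepoint.
#'
#' @param registered a [register_cells()] result.
#' @return data.frame with columns `time_h`, `on_live`, `on_dead`,
#'   `off_live`, `off_dead`, `total`.
#' @export
registration_summary <- function(registered) {
  stopifnot(inherits(registered, "registered_cells"))
  viab <- if ("viability" %in% names(registered)) registered$viability
          else rep("live", nrow(registered))
  tms <- sort(unique(registered$time_h))
  do.call(rbind, lapply(tms, function(t) {
    s <- registered$time_h == t
    data.frame(time_h = t,
               on_live = sum(s & registered$on_disc & viab == "live"),
               on_dead = sum(s & registered$on_disc & viab == "dead"),
               off_live = sum(s & !registered$on_disc & viab == "live"),
               off_dead = sum(s & !registered$on_disc & viab == "dead"),
               total = sum(s))
  }))
}

#' On-disc live-cell growth curve
#'
#' Counts live on-disc cells at every timepoint of a registered detection
#' table, producing the growth curve the exponential fit consumes.  Dead
#' cells and off-disc cells are excluded from the counts; timepoints where
#' every detection is off-disc contribute a zero count.
#'
#' @param registered a [register_cells()] result spanning >= 2 distinct
#'   timepoints (column `time_h` required).
#' @return a [growth_curve()] of live on-disc counts, sorted by time.  If
#'   all counts are zero the curve carries attribute `all_zero = TRUE`.
#' @export
on_disc_growth_curve <- function(registered) {
  stopifnot(inherits(registered, "registered_cells"))
  if (!"time_h" %in% names(registered)) stop("registered cells need a time_h column")
  tms <- sort(unique(registered$time_h))
  if (length(tms) < 2L) stop("need >= 2 distinct timepoints")
  viab <- if ("viability" %in% names(registered)) registered$viability
          else rep("live", nrow(registered))
  counts <- vapply(tms, function(t) {
    sum(registered$time_h == t & registered$on_disc & viab == "live")
  }, numeric(1))
  gc <- growth_curve(tms, counts)
  if (all(counts == 0)) attr(gc, "all_zero") <- TRUE
  gc
}
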