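roi_mask <- function(mask, kind, pixel_mm, contour_id = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask),
            kind %in% c("internal", "external"))
  structure(list(mask = mask, kind = kind, pixel_mm = pixel_mm,
                 contour_id = contour_id),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %d px (%.1f mm^2)\n", x$kind, sum(x$mask),
              sum(x$mask) * x$pixel_mm^2))
  invisible(x)
}

#' Rasterize a closed contour polygon to an internal ROI mask
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon under
#' the even-odd rule. The polygon must be closed (last vertex repeats the
#' first), have at least 3 distinct vertices, and be free of
#' self-intersections.
#'
#' @param polygon `n x 2` matrix of (x_mm, z_mm) vertices, closed.
#' @param grid_shape (rows, cols) of the pixel grid.
#' @param pixel_mm isotropic pixel spacing; pixel (r, c) has centre
#'   `((c - 0.5) * pixel_mm, (r - 0.5) * pixel_mm)`.
#' @param contour_id optional identifier carried on the mask.
#' @return A `roi_mask` of kind `"internal"`.
#' @export
rasterize_contour <- function(polygon, grid_shape, pixel_mm,
                              contour_id = NULL) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 4L) {
    stopf("`polygon` must be a closed (x, z) vertex matrix with >= 3 vertices")
  }
  if (max(abs(polygon[1L, ] - polygon[nrow(polygon), ])) > 1e-9) {
    stopf("polygon is not closed (last vertex must repeat the first)")
  }
  ring <- polygon[-nrow(polygon), , drop = FALSE]
  if (nrow(unique(ring)) < 3L) stopf("polygon has fewer than 3 distinct vertices")
  if (polygon_self_intersects(ring)) stopf("polygon is self-intersecting")

  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  inside <- matrix(FALSE, nr, nc)
  # only pixel centres inside the contour's bounding box can be inside
  cr <- range(ring[, 2L]) / pixel_mm + 0.5
  cc <- range(ring[, 1L]) / pixel_mm + 0.5
  if (cr[2L] >= 1 && cr[1L] <= nr && cc[2L] >= 1 && cc[1L] <= nc) {
    rows <- max(1L, floor(cr[1L])):min(nr, ceiling(cr[2L]))
    cols <- max(1L, floor(cc[1L])):min(nc, ceiling(cc[2L]))
    xc <- (cols - 0.5) * pixel_mm
    zc <- (rows - 0.5) * pixel_mm
    px <- rep(xc, each = length(rows))
    pz <- rep(zc, times = length(cols))
    inside[rows, cols] <- points_in_polygon(px, pz, ring)
  }
  if (!any(inside)) warnf("contour covers no pixel centre; empty mask")
  roi_mask(inside, "internal", pixel_mm, contour_id)
}

#' Build the external (peritumoral rim) ROI
#'
#' Pixels whose Euclidean distance to the internal mask lies in
#' `(0, rim_width_mm]`, computed with an exact distance transform on the
#' pixel grid, minus any exclusion masks (e.g. a skin band or shadow
#' regions). Internal and external masks are disjoint by construction.
#'
#' @param internal an internal `roi_mask`.
#' @param rim_width_mm rim thickness in mm (default 5).
#' @param exclusions optional list of logical matrices (or `roi_mask`s) to
#'   remove from the rim.
#' @return A `roi_mask` of kind `"external"`.
#' @export
external_rim <- function(internal, rim_width_mm = 5, exclusions = NULL) {
  stopifnot(inherits(internal, "roi_mask"))
  if (!any(internal$mask)) stopf("internal mask is empty; no rim can be built")
  if (rim_width_mm < 0) stopf("`rim_width_mm` must be >= 0")
  d <- distance_to_mask(internal$mask, internal$pixel_mm)
  rim <- !internal$mask & d > 0 & d <= rim_width_mm
  if (!is.null(exclusions)) {
    for (ex in exclusions) {
      m <- if (inherits(ex, "roi_mask")) ex$mask else ex
      stopifnot(identical(dim(m), dim(rim)))
      rim <- rim & !m
    }
  }
  if (!any(rim)) warnf("external rim mask is empty")
  roi_mask(rim, "external", internal$pixel_mm, internal$contour_id)
}

#' Exclusion mask for a superficial (skin) band
#'
#' Optional helper flagging the top `depth_mm` of the image, for removal
#' from external rims of shallow lesions where the rim would include skin.
#'
#' @param grid_shape (rows, cols).
#' @param pixel_mm pixel spacing.
#' @param depth_mm band depth from the top of the image.
#' @return Logical matrix.
#' @export
skin_band_exclusion <- function(grid_shape, pixel_mm, depth_mm) {
  nr <- grid_shape[1L]
  zc <- (seq_len(nr) - 0.5) * pixel_mm
  matrix(zc <= depth_mm, nr, grid_shape[2L])
}

#' Place sliding analysis windows
#'
#' Regular raster of square windows of physical size `window_mm` with the
#' given fractional overlap; the stride is
#' `round(window_px * (1 - overlap))`, clamped to at least 1 pixel, and
#' windows lie fully inside the image.
#'
#' @param grid_shape (rows, cols) of the pixel grid.
#' @param pixel_mm isotropic pixel spacing.
#' @param window_mm window side length in mm (default 1).
#' @param overlap fractional overlap in each direction (default 0.92).
#' @return A `window_grid`: window/stride in px and start indices per axis.
#' @export
place_windows <- function(grid_shape, pixel_mm, window_mm = 1,
                          overlap = 0.92) {
  check_scalar_pos(window_mm, "window_mm")
  if (overlap < 0 || overlap >= 1) stopf("`overlap` must be in [0, 1)")
  wp <- max(2L, as.integer(round(window_mm / pixel_mm)))
  if (wp > min(grid_shape)) {
    stopf("window (%d px) larger than image (%d x %d px)",
          wp, grid_shape[1L], grid_shape[2L])
  }
  stride <- max(1L, as.integer(round(wp * (1 - overlap))))
  row_start <- seq.int(1L, grid_shape[1L] - wp + 1L, by = stride)
  col_start <- seq.int(1L, grid_shape[2L] - wp + 1L, by = stride)
  structure(list(grid_shape = as.integer(grid_shape), pixel_mm = pixel_mm,
                 window_mm = window_mm, overlap = overlap,
                 window_px = wp, stride_px = stride,
                 row_start = as.integer(row_start),
                 col_start = as.integer(col_start)),
            class = "window_grid")
}

# Centre pixel of a window starting at `start` (1-based).
window_centers <- function(windows) {
  off <- windows$window_px %/% 2L
  list(row = windows$row_start + off, col = windows$col_start + off)
}

#' Assign windows to an ROI
#'
#' A window belongs to the ROI iff its centre pixel is inside the ROI mask
#' (an unbiased rule between interior and rim; a minimum-overlap rule can
#' be selected instead).
#'
#' @param windows a [place_windows()] grid.
#' @param roi a `roi_mask` on the same pixel grid.
#' @param rule `"center"` (default) or `"overlap"`.
#' @param min_overlap minimum fraction of window pixels inside the mask
#'   when `rule = "overlap"` (default 0.5).
#' @return Data frame with one row per assigned window: `ai`, `li` (axial /
#'   lateral placement indices), `row`, `col` (start pixel), `cr`, `cc`
#'   (centre pixel).
#' @export
assign_windows <- function(windows, roi, rule = c("center", "overlap"),
                           min_overlap = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(windows, "window_grid"), inherits(roi, "roi_mask"))
  if (!identical(dim(roi$mask), as.integer(windows$grid_shape)) ||
      abs(roi$pixel_mm - windows$pixel_mm) > 1e-12) {
    stopf("window grid and ROI mask are on different pixel grids")
  }
  ctr <- window_centers(windows)
  na <- length(windows$row_start); nl <- length(windows$col_start)
  ai <- rep(seq_len(na), times = nl)
  li <- rep(seq_len(nl), each = na)
  cr <- ctr$row[ai]; cc <- ctr$col[li]
  keep <- if (rule == "center") {
    roi$mask[cbind(cr, cc)]
  } else {
    wp <- windows$window_px
    vapply(seq_along(ai), function(q) {
      r0 <- windows$row_start[ai[q]]; c0 <- windows$col_start[li[q]]
      mean(roi$mask[r0:(r0 + wp - 1L), c0:(c0 + wp - 1L)]) >= min_overlap
    }, logical(1))
  }
  data.frame(ai = ai[keep], li = li[keep],
             row = windows$row_start[ai[keep]],
             col = windows$col_start[li[keep]],
             cr = cr[keep], cc = cc[keep])
}
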