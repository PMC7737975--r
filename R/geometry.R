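# Contour geometry: spline-based perimeters/areas from marker contours and
# convex-hull-based perimeters/areas from binary masks. All lengths are
# returned in cm and areas in cm^2 (inputs are mm); the unit conversion
# happens here and nowhere else.

polyline_length <- function(pts) {
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

closed_polygon_length <- function(pts) {
  polyline_length(rbind(pts, pts[1, , drop = FALSE]))
}

# Signed shoelace area of a closed polygon (points not repeated at the end).
shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

drop_duplicate_points <- function(pts) {
  n <- nrow(pts)
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 1 && all(pts[nrow(pts), ] == pts[1, ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

is_collinear <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 3) return(TRUE)
  v <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cross <- v[-1, 1] * v[1, 2] - v[-1, 2] * v[1, 1]
  scale <- max(abs(v)) ^ 2
  all(abs(cross) <= tol * max(scale, 1))
}

#' Resample a marker contour along its closed periodic cubic spline
#'
#' Interpolates the marker points with a closed periodic cubic spline under
#' uniform chord-length parameterisation and returns a dense polyline along it.
#'
#' @param pts An `n x 2` matrix of marker points in mm (closure implied).
#' @param samples_per_segment Dense samples per marker-to-marker segment; 200
#'   bounds the relative arc-length error well below 1e-4 for LV-like contours.
#' @return A dense `(n * samples_per_segment + 1) x 2` matrix tracing the
#'   closed curve (first point repeated at the end).
#' @export
resample_contour <- function(pts, samples_per_segment = 200) {
  pts <- drop_duplicate_points(unclass(pts))
  n <- nrow(pts)
  if (n < 3) stop("at least 3 distinct points are required")
  p <- rbind(pts, pts[1, , drop = FALSE])
  tt <- c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-(n + 1), , drop = FALSE])^2))))
  u <- seq(0, tt[n + 1], length.out = n * samples_per_segment + 1)
  cbind(stats::spline(tt, p[, 1], method = "periodic", xout = u)$y,
        stats::spline(tt, p[, 2], method = "periodic", xout = u)$y)
}

#' Spline perimeter of a marker contour
#'
#' Arc length of the closed periodic cubic interpolant through the marker
#' points, the contour model used by marker-based contouring software.
#' Collinear (degenerate) marker sets fall back to the closed polygon length
#' with a warning.
#'
#' @inheritParams resample_contour
#' @param contour An `n x 2` matrix of marker points in mm.
#' @return Perimeter in cm.
#' @export
spline_perimeter <- function(contour, samples_per_segment = 200) {
  pts <- drop_duplicate_points(unclass(contour))
  if (nrow(pts) < 3) stop("at least 3 distinct points are required")
  if (is_collinear(pts)) {
    warning("collinear contour points; falling back to polygon perimeter")
    return(closed_polygon_length(pts) / 10)
  }
  polyline_length(resample_contour(pts, samples_per_segment)) / 10
}

#' Spline-enclosed area of a marker contour
#'
#' Shoelace area of the densely resampled closed interpolant (absolute value,
#' so the result is orientation-invariant).
#'
#' @inheritParams spline_perimeter
#' @return Area in cm^2.
#' @export
spline_area <- function(contour, samples_per_segment = 200) {
  pts <- drop_duplicate_points(unclass(contour))
  if (nrow(pts) < 3) stop("at least 3 distinct points are required")
  if (is_collinear(pts)) {
    warning("collinear contour points; enclosed area is 0")
    return(0)
  }
  dense <- resample_contour(pts, samples_per_segment)
  abs(shoelace_area(dense[-nrow(dense), , drop = FALSE])) / 100
}

mask_foreground_coords <- function(mask, pixel_spacing,
                                   convention = c("centers", "corners")) {
  convention <- match.arg(convention)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  if (convention == "centers") {
    (idx - 0.5) * pixel_spacing
  } else {
    do.call(rbind, lapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), function(off) {
      cbind((idx[, 1] - 1 + off[1]) * pixel_spacing,
            (idx[, 2] - 1 + off[2]) * pixel_spacing)
    }))
  }
}

hull_polygon <- function(mask, pixel_spacing, convention = "centers") {
  coords <- mask_foreground_coords(mask, pixel_spacing, convention)
  if (nrow(coords) == 0) stop("empty mask: no foreground pixels")
  if (nrow(coords) < 3 || is_collinear(unique(coords))) {
    warning("fewer than 3 non-collinear foreground pixels; degenerate hull")
    return(NULL)
  }
  coords[rev(grDevices::chull(coords)), , drop = FALSE]  # counter-clockwise
}

#' Convex-hull perimeter of a binary mask slice
#'
#' Perimeter of the convex hull of the foreground pixel coordinates, the
#' contour-length measure used when segmentations are exported as binary
#' images. By default hulls are taken over pixel centres (at
#' `(i - 1/2) * pixel_spacing`); `convention = "corners"` hulls the pixel
#' corner points instead, which lengthens the result by about one pixel of
#' perimeter.
#'
#' @param mask A binary matrix (0 background, non-zero foreground).
#' @param pixel_spacing Pixel size in mm; defaults to the mask's
#'   `pixel_spacing` attribute.
#' @param convention `"centers"` (default) or `"corners"`.
#' @return Hull perimeter in cm (0 with a warning for degenerate masks).
#' @export
hull_perimeter <- function(mask, pixel_spacing = attr(mask, "pixel_spacing"),
                           convention = "centers") {
  if (is.null(pixel_spacing)) stop("pixel_spacing is required")
  hull <- hull_polygon(mask, pixel_spacing, convention)
  if (is.null(hull)) return(0)
  closed_polygon_length(hull) / 10
}

#' Convex-hull area of a binary mask slice
#'
#' Area of the same hull polygon as [hull_perimeter()], in cm^2.
#'
#' @inheritParams hull_perimeter
#' @return Hull area in cm^2 (0 with a warning for degenerate masks).
#' @export
hull_area <- function(mask, pixel_spacing = attr(mask, "pixel_spacing"),
                      convention = "centers") {
  if (is.null(pixel_spacing)) stop("pixel_spacing is required")
  hull <- hull_polygon(mask, pixel_spacing, convention)
  if (is.null(hull)) return(0)
  abs(shoelace_area(hull)) / 100
}
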