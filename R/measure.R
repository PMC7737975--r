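# Per-slice measurement layer: turn a session's contours or masks into one
# perimeter/area record per (slice, frame).

#' Measure every slice and frame of a session
#'
#' Runs the chosen measurement chain over a complete slice-by-frame session:
#' `method = "spline"` measures the marker contours with the periodic cubic
#' spline ([spline_perimeter()] / [spline_area()]); `method = "hull"` measures
#' the convex hull of the binary masks ([hull_perimeter()] / [hull_area()]),
#' rasterising the contours on the fly when the session carries none.
#'
#' @param session An `lv_session` from [generate_study()] (or a compatible list
#'   with a `contours` tibble of `slice`, `frame`, `points`).
#' @param method `"spline"` or `"hull"`.
#' @param config A [phantom_config()]; required for `method = "hull"` when
#'   masks must be rasterised from contours.
#' @param samples_per_segment Spline resampling density, see
#'   [resample_contour()].
#' @param hull_convention Hull point convention, see [hull_perimeter()].
#' @return A tibble with one row per (slice, frame): `slice`, `frame`,
#'   `method`, `perimeter_cm`, `area_cm2`.
#' @export
measure_session <- function(session, method = c("spline", "hull"), config = NULL,
                            samples_per_segment = 200,
                            hull_convention = "centers") {
  method <- match.arg(method)
  contours <- session$contours
  stopifnot(is.data.frame(contours),
            all(c("slice", "frame", "points") %in% names(contours)))
  check_complete_grid(contours$slice, contours$frame)
  if (method == "spline") {
    meas <- vapply(contours$points, function(p) {
      dense <- resample_contour(p, samples_per_segment)
      c(polyline_length(dense) / 10,
        abs(shoelace_area(dense[-nrow(dense), , drop = FALSE])) / 100)
    }, numeric(2))
  } else {
    meas <- mapply(function(p, s, f) {
      mask <- if (!is.null(session$masks)) {
        m <- session$masks[, , s, f]
        attr(m, "pixel_spacing") <- config$pixel_spacing
        m
      } else {
        if (is.null(config)) stop("config is required to rasterise contours for hull measurement")
        rasterize_mask(p, config)
      }
      c(hull_perimeter(mask, convention = hull_convention),
        hull_area(mask, convention = hull_convention))
    }, contours$points, contours$slice, contours$frame)
  }
  tibble::tibble(slice = contours$slice, frame = contours$frame,
                 method = method,
                 perimeter_cm = meas[1, ], area_cm2 = meas[2, ]) |>
    dplyr::arrange(.data$slice, .data$frame)
}

check_complete_grid <- function(slice, frame) {
  want <- expand.grid(slice = sort(unique(slice)), frame = sort(unique(frame)))
  have <- paste(slice, frame)
  gaps <- setdiff(paste(want$slice, want$frame), have)
  if (length(gaps))
    stop("incomplete session; missing (slice, frame): ",
         paste(gaps, collapse = "; "))
  if (anyDuplicated(have))
    stop("duplicated (slice, frame) entries in session")
  invisible(TRUE)
}

#' Measure every session of a simulated study
#'
#' @param study An `lv_study` from [generate_study()].
#' @param method Measurement chain for every session, see [measure_session()].
#' @param ... Passed to [measure_session()].
#' @return A tibble with session metadata (`session_id`, `reader`, `software`,
#'   `repetition`, `type`) joined to the per-slice measurements.
#' @export
measure_study <- function(study, method = "spline", ...) {
  dplyr::bind_rows(lapply(study$sessions, function(s) {
    dplyr::bind_cols(
      tibble::tibble(session_id = s$session_id, reader = s$reader,
                     software = s$software, repetition = s$repetition,
                     type = s$type),
      measure_session(s, method = method, config = study$config, ...))
  }))
}
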