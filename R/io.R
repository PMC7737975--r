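# On-disk formats: contour JSON, NIfTI mask stacks, CSV tables, YAML config.

#' Write a session's contours as JSON
#'
#' Layout: `{"session": {"reader", "software", "repetition", "type"},
#' "slices": [{"slice", "frame", "points": [[x_mm, y_mm], ...]}, ...]}`.
#'
#' @param session An `lv_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(session, path) {
  payload <- list(
    session = list(reader = session$reader, software = session$software,
                   repetition = session$repetition, type = session$type),
    slices = lapply(seq_len(nrow(session$contours)), function(i) {
      list(slice = session$contours$slice[i],
           frame = session$contours$frame[i],
           points = unname(apply(unclass(session$contours$points[[i]]), 1,
                                 function(p) c(p[1], p[2]), simplify = FALSE)))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a session's contours from JSON
#'
#' Contour orientation is normalised counter-clockwise on load.
#'
#' @param path A file written by [write_contours_json()].
#' @return An `lv_session` (without masks).
#' @export
read_contours_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  contours <- lapply(raw$slices, function(sl) {
    pts <- do.call(rbind, lapply(sl$points, function(p) as.numeric(unlist(p))))
    colnames(pts) <- c("x", "y")
    if (shoelace_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    pts
  })
  session <- list(
    session_id = sprintf("%s_T%d_R%02d", raw$session$software,
                         raw$session$repetition, raw$session$reader),
    reader = as.integer(raw$session$reader),
    software = raw$session$software,
    repetition = as.integer(raw$session$repetition),
    type = raw$session$type,
    contours = tibble::tibble(
      slice = vapply(raw$slices, function(sl) as.integer(sl$slice), 1L),
      frame = vapply(raw$slices, function(sl) as.integer(sl$frame), 1L),
      points = contours))
  class(session) <- "lv_session"
  session
}

#' Write a session's mask stack as NIfTI
#'
#' One 4-D volume (x, y, slice, frame), with the in-plane pixel spacing and the
#' effective slice spacing encoded in the voxel dimensions.
#'
#' @param masks A 4-D array (x, y, slice, frame) of 0/1.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixel_spacing In-plane spacing, mm.
#' @param slice_spacing Effective slice spacing, mm.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(masks, path, pixel_spacing = 1.6, slice_spacing = 10) {
  stopifnot(length(dim(masks)) == 4)
  img <- RNifti::asNifti(masks * 1)
  RNifti::pixdim(img) <- c(pixel_spacing, pixel_spacing, slice_spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask stack from NIfTI
#'
#' @param path A file written by [write_mask_nifti()].
#' @return A list: `masks` (4-D integer array), `pixel_spacing`,
#'   `slice_spacing`.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.integer(img != 0), dim = dim(img))
  list(masks = arr, pixel_spacing = pd[1], slice_spacing = pd[3])
}

#' Write the phantom ground truth as CSV
#'
#' Per-slice rows (`slice`, `frame`, `radius_mm`, `perimeter_cm`, `area_cm2`)
#' followed, in a companion file, by the single analytic metrics row.
#'
#' @param truth The `truth` element of an `lv_study`.
#' @param path Output CSV path for the per-slice table; the metrics row is
#'   written next to it with suffix `_metrics.csv`.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  readr::write_csv(truth$table, path)
  readr::write_csv(truth$metrics,
                   sub("\\.csv$", "_metrics.csv", path))
  invisible(path)
}

#' Read or write a phantom configuration as YAML
#'
#' The YAML mirrors the [phantom_config()] argument names; `slice_offsets` is
#' derived and not serialised.
#'
#' @param config A [phantom_config()].
#' @param path File path.
#' @return `read_phantom_config()` returns a [phantom_config()];
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
write_phantom_config <- function(config, path) {
  fields <- config[setdiff(names(config), "slice_offsets")]
  fields$region_peak_strain <- as.list(fields$region_peak_strain)
  fields$software_length_bias <- as.list(fields$software_length_bias)
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  fields <- yaml::read_yaml(path)
  fields$region_peak_strain <- unlist(fields$region_peak_strain)
  fields$software_length_bias <- unlist(fields$software_length_bias)
  do.call(phantom_config, fields)
}
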