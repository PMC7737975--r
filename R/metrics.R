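# Clinical metric layer: composite midpoint volumes, ED/ES detection, LVEF,
# circumferential strain with regional grouping.

#' Left-ventricular volume curve by composite midpoint integration
#'
#' For each frame the cavity volume is the sum over slices of the enclosed
#' area times the effective slice spacing (slice thickness + gap):
#' `V(f) = sum_s A(s, f) * slice_spacing / 10` in mL (cm^2 x cm).
#' End-diastole is the frame of maximum volume and end-systole the frame of
#' minimum volume, with ties broken towards the earliest frame.
#'
#' @param measurements A tibble with columns `slice`, `frame`, `area_cm2`
#'   covering a complete slice-by-frame grid.
#' @param slice_spacing Effective slice spacing in mm.
#' @return A list with `volume_ml` (named by frame), `ed_frame`, `es_frame`.
#' @export
volume_curve <- function(measurements, slice_spacing = 10) {
  stopifnot(slice_spacing > 0)
  if (anyNA(measurements$area_cm2)) stop("missing areas in measurements")
  check_complete_grid(measurements$slice, measurements$frame)
  frames <- sort(unique(measurements$frame))
  vol <- vapply(frames, function(f) {
    sum(measurements$area_cm2[measurements$frame == f]) * slice_spacing / 10
  }, 0)
  names(vol) <- frames
  list(volume_ml = vol,
       ed_frame = frames[which.max(vol)],
       es_frame = frames[which.min(vol)])
}

#' Left ventricular ejection fraction
#'
#' `LVEF = 100 * (EDV - ESV) / EDV` in percent.
#'
#' @param edv End-diastolic volume, mL (> 0).
#' @param esv End-systolic volume, mL (must not exceed `edv`).
#' @return LVEF in percent.
#' @export
lvef <- function(edv, esv) {
  if (any(edv <= 0)) stop("EDV must be positive")
  if (any(esv > edv))
    stop("ESV exceeds EDV; ED/ES frame definition violated upstream")
  100 * (edv - esv) / edv
}

#' Per-slice circumferential strain matrix
#'
#' Circumferential strain of slice `s` at frame `n` is the fractional change of
#' its endocardial perimeter relative to the end-diastolic reference:
#' `strain(s, n) = (L(s, n) - L(s, ED)) / L(s, ED)`. The reference frame is
#' global (one ED frame from the summed volume curve), so the strain at ED is
#' exactly zero for every slice.
#'
#' @param measurements A tibble with columns `slice`, `frame`, `perimeter_cm`.
#' @param ed_frame The end-diastolic reference frame index.
#' @return A tibble `slice`, `frame`, `strain` (dimensionless) with attribute
#'   `ed_frame`.
#' @export
strain_matrix <- function(measurements, ed_frame) {
  check_complete_grid(measurements$slice, measurements$frame)
  if (!ed_frame %in% measurements$frame) stop("ed_frame not present in measurements")
  ref <- measurements[measurements$frame == ed_frame,
                      c("slice", "perimeter_cm")]
  names(ref)[2] <- "L0"
  bad <- ref$slice[ref$L0 <= 0]
  if (length(bad))
    stop("non-positive ED perimeter for slice(s): ", paste(bad, collapse = ", "))
  out <- dplyr::inner_join(
    measurements[, c("slice", "frame", "perimeter_cm")], ref, by = "slice")
  out <- tibble::tibble(slice = out$slice, frame = out$frame,
                        strain = (out$perimeter_cm - out$L0) / out$L0) |>
    dplyr::arrange(.data$slice, .data$frame)
  attr(out, "ed_frame") <- ed_frame
  out
}

#' Regional and global strain curves
#'
#' The strain curve of a region is the unweighted mean over its slices of the
#' per-slice strains, frame by frame; the global curve is the unweighted mean
#' over all slices.
#'
#' @param strains A strain tibble from [strain_matrix()].
#' @param regions A slice-to-region factor from [region_map()] (indexed by
#'   slice number).
#' @return A tibble `region` (`base`, `mid`, `apex`, `global`), `frame`,
#'   `strain`.
#' @export
regional_strain_curves <- function(strains, regions) {
  slices <- sort(unique(strains$slice))
  if (max(slices) > length(regions)) stop("regions does not cover all slices")
  reg <- regions[strains$slice]
  if (any(table(regions[slices]) == 0)) stop("empty region")
  regional <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(region = as.character(reg), frame = strains$frame,
                     strain = strains$strain),
      .data$region, .data$frame),
    strain = mean(.data$strain), .groups = "drop")
  global <- dplyr::summarise(dplyr::group_by(strains, .data$frame),
                             strain = mean(.data$strain), .groups = "drop")
  dplyr::bind_rows(regional,
                   tibble::tibble(region = "global", frame = global$frame,
                                  strain = global$strain)) |>
    dplyr::mutate(region = factor(.data$region,
                                  levels = c("base", "mid", "apex", "global"))) |>
    dplyr::arrange(.data$region, .data$frame)
}

#' Peak circumferential strain of a curve
#'
#' The peak is the most negative value of the per-frame strain curve, reported
#' in percent (sign preserved; negative means shortening).
#'
#' @param curve Numeric vector of per-frame strains (dimensionless).
#' @return Peak strain in percent.
#' @export
peak_strain <- function(curve) {
  100 * min(curve)
}

#' Clinical metrics of one contouring session
#'
#' Composes the full measurement-to-metrics chain: composite midpoint volume
#' curve, ED/ES detection, LVEF, per-slice strain relative to the global ED
#' frame, regional/global strain curves, and peak strains.
#'
#' @param measurements A tibble with columns `slice`, `frame`, `perimeter_cm`,
#'   `area_cm2` for one session (complete grid).
#' @param slice_spacing Effective slice spacing in mm.
#' @param regions Slice-to-region assignment, see [region_map()].
#' @param peak_method `"regional_curve"` (default): average slices into the
#'   regional curve first, then take its extremum; `"per_slice"`: take each
#'   slice's extremum first, then average within the region.
#' @return A one-row tibble: `ACS`, `MCS`, `BCS`, `GCS` (percent, negative for
#'   contraction), `EDV`, `ESV` (mL), `LVEF` (percent), `ed_frame`, `es_frame`.
#' @export
clinical_metrics <- function(measurements, slice_spacing = 10,
                             regions = region_map(length(unique(measurements$slice))),
                             peak_method = c("regional_curve", "per_slice")) {
  peak_method <- match.arg(peak_method)
  vc <- volume_curve(measurements, slice_spacing)
  edv <- unname(vc$volume_ml[as.character(vc$ed_frame)])
  esv <- unname(vc$volume_ml[as.character(vc$es_frame)])
  strains <- strain_matrix(measurements, vc$ed_frame)
  if (peak_method == "regional_curve") {
    curves <- regional_strain_curves(strains, regions)
    peak_of <- function(reg) {
      peak_strain(curves$strain[curves$region == reg])
    }
    acs <- peak_of("apex"); mcs <- peak_of("mid"); bcs <- peak_of("base")
    gcs <- peak_of("global")
  } else {
    per_slice <- dplyr::summarise(dplyr::group_by(strains, .data$slice),
                                  peak = peak_strain(.data$strain),
                                  .groups = "drop")
    reg <- regions[per_slice$slice]
    acs <- mean(per_slice$peak[reg == "apex"])
    mcs <- mean(per_slice$peak[reg == "mid"])
    bcs <- mean(per_slice$peak[reg == "base"])
    gcs <- mean(per_slice$peak)
  }
  tibble::tibble(ACS = acs, MCS = mcs, BCS = bcs, GCS = gcs,
                 EDV = edv, ESV = esv, LVEF = lvef(edv, esv),
                 ed_frame = vc$ed_frame, es_frame = vc$es_frame)
}

#' Clinical metrics for every session of a measured study
#'
#' @param measurements Output of [measure_study()] (session metadata plus
#'   per-slice measurements).
#' @param slice_spacing Effective slice spacing in mm.
#' @param ... Passed to [clinical_metrics()].
#' @return A tibble with one row per session: metadata plus the seven metrics.
#' @export
study_metrics <- function(measurements, slice_spacing = 10, ...) {
  meta_cols <- c("session_id", "reader", "software", "repetition", "type")
  stopifnot(all(meta_cols %in% names(measurements)))
  measurements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::group_modify(function(d, key) {
      clinical_metrics(d, slice_spacing = slice_spacing, ...)
    }) |>
    dplyr::ungroup()
}
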