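#' Configure the deformable left-ventricle phantom
#'
#' The phantom models the LV cavity as an ellipsoid cap sampled by a short-axis
#' stack: slice `s` (1 = most basal) sits at long-axis offset
#' `z_s = (s - 1/2) * slice_spacing` and has end-diastolic radius
#' `r0(s) = base_radius * sqrt(1 - (z_s / cap_half_height)^2)`. Over the cine
#' frames each slice's radius shortens following a raised-cosine half-cycle
#' towards a region-specific peak circumferential strain, so frame 1 is
#' end-diastole (strain exactly 0) and the last frame is end-systole.
#'
#' Reader variability is a smooth zero-mean angular perturbation of the contour
#' radius (low-order Fourier modes, scaled to `reader_noise_sd`); per-software
#' systematic contour-length biases are injected as a uniform radial offset of
#' `bias_cm * 10 / (2 * pi)` mm, i.e. additive in circumference.
#'
#' @param n_slices Number of short-axis slices; must be divisible by 3 so the
#'   stack splits into equal basal / mid-ventricular / apical regions.
#' @param n_frames Number of cine frames from just before end-diastole to just
#'   after end-systole.
#' @param pixel_spacing In-plane pixel size in mm.
#' @param slice_spacing Effective slice spacing in mm (slice thickness + gap).
#' @param grid_size Mask grid side length in pixels.
#' @param base_radius Maximal end-diastolic cavity radius in mm.
#' @param cap_half_height Ellipsoid-cap semi-axis along the long axis, mm.
#' @param region_peak_strain Named numeric vector with elements `base`, `mid`,
#'   `apex`: peak (end-systolic) circumferential strain per region, each in
#'   (-1, 0].
#' @param reader_noise_sd Angular RMS of the radial reader perturbation, mm.
#' @param reader_noise_modes Number of angular Fourier modes in the
#'   perturbation field.
#' @param software_length_bias Named numeric vector of additive contour-length
#'   biases in cm, one element per manual-contouring software label.
#' @param automated_label Label of the single automated (zero reader noise)
#'   session.
#' @param automated_length_bias Additive contour-length bias of the automated
#'   software, cm.
#' @param n_readers Number of readers.
#' @param n_repetitions Contouring repetitions per reader per software.
#' @param n_markers Contour control points per slice.
#' @param seed Master seed; every contour draws from a substream derived from
#'   it, so sessions are independent and order-insensitive.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 9,
                           n_frames = 16,
                           pixel_spacing = 1.6,
                           slice_spacing = 10,
                           grid_size = 128,
                           base_radius = 28,
                           cap_half_height = 100,
                           region_peak_strain = c(base = -0.30, mid = -0.20, apex = -0.12),
                           reader_noise_sd = 1.0,
                           reader_noise_modes = 3,
                           software_length_bias = c(OsiriX = 0, ScanIP = -1.9),
                           automated_label = "CVI42",
                           automated_length_bias = -0.6,
                           n_readers = 7,
                           n_repetitions = 2,
                           n_markers = 24,
                           seed = 1L) {
  stopifnot(n_slices >= 3, n_frames >= 2, base_radius > 0, pixel_spacing > 0,
            slice_spacing > 0, cap_half_height > 0, n_markers >= 3,
            n_readers >= 1, n_repetitions >= 1, reader_noise_sd >= 0,
            reader_noise_modes >= 1)
  if (n_slices %% 3 != 0)
    stop("n_slices must be divisible by 3 (equal base/mid/apex regions)")
  if (!all(c("base", "mid", "apex") %in% names(region_peak_strain)))
    stop("region_peak_strain must have elements named base, mid, apex")
  if (any(region_peak_strain > 0) || any(region_peak_strain <= -1))
    stop("region_peak_strain values must lie in (-1, 0]")
  if (is.null(names(software_length_bias)) || any(names(software_length_bias) == ""))
    stop("software_length_bias must be a named vector of biases in cm")
  if (automated_label %in% names(software_length_bias))
    stop("automated_label must differ from the manual software labels")
  z <- (seq_len(n_slices) - 0.5) * slice_spacing
  if (max(z) >= cap_half_height)
    stop("degenerate apex: the most apical slice offset (", max(z),
         " mm) reaches cap_half_height; enlarge cap_half_height or reduce slices")
  if (base_radius + 4 * reader_noise_sd >= grid_size * pixel_spacing / 2)
    stop("grid too small: base_radius + 4*reader_noise_sd must fit inside half the grid")
  structure(
    list(n_slices = as.integer(n_slices), n_frames = as.integer(n_frames),
         pixel_spacing = pixel_spacing, slice_spacing = slice_spacing,
         grid_size = as.integer(grid_size), base_radius = base_radius,
         cap_half_height = cap_half_height,
         region_peak_strain = region_peak_strain[c("base", "mid", "apex")],
         reader_noise_sd = reader_noise_sd,
         reader_noise_modes = as.integer(reader_noise_modes),
         software_length_bias = software_length_bias,
         automated_label = automated_label,
         automated_length_bias = automated_length_bias,
         n_readers = as.integer(n_readers),
         n_repetitions = as.integer(n_repetitions),
         n_markers = as.integer(n_markers),
         slice_offsets = z,
         seed = as.integer(seed)),
    class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("LV phantom configuration\n")
  cat(sprintf("  stack: %d slices x %d frames, %.1f mm pixels, %.1f mm slice spacing\n",
              x$n_slices, x$n_frames, x$pixel_spacing, x$slice_spacing))
  cat(sprintf("  geometry: base radius %.1f mm, cap half-height %.1f mm\n",
              x$base_radius, x$cap_half_height))
  cat(sprintf("  peak strains: base %.2f, mid %.2f, apex %.2f\n",
              x$region_peak_strain[["base"]], x$region_peak_strain[["mid"]],
              x$region_peak_strain[["apex"]]))
  cat(sprintf("  readers: %d x %d repetitions, noise SD %.2f mm (%d modes)\n",
              x$n_readers, x$n_repetitions, x$reader_noise_sd, x$reader_noise_modes))
  cat("  software length bias (cm):",
      paste(sprintf("%s=%.2f", names(x$software_length_bias), x$software_length_bias),
            collapse = ", "),
      sprintf("| automated %s=%.2f\n", x$automated_label, x$automated_length_bias))
  invisible(x)
}

#' Map slices to ventricular regions
#'
#' Slices are split into three contiguous equal blocks: slice 1 is the most
#' basal, so the first block is `base`, then `mid`, then `apex`.
#'
#' @param n_slices Number of slices (divisible by 3).
#' @return A factor of length `n_slices` with levels `base`, `mid`, `apex`.
#' @export
region_map <- function(n_slices = 9) {
  if (n_slices %% 3 != 0) stop("n_slices must be divisible by 3")
  factor(rep(c("base", "mid", "apex"), each = n_slices / 3),
         levels = c("base", "mid", "apex"))
}

#' Noise-free phantom radius
#'
#' `r(s, f) = r0(s) * (1 + eps_region(s) * g(f))` with
#' `g(f) = (1 - cos(pi * (f - 1) / (n_frames - 1))) / 2`, so `g` rises smoothly
#' from 0 at the first frame (end-diastole) to 1 at the last (end-systole).
#'
#' @param config A [phantom_config()].
#' @param slice Slice index (1-based, 1 = most basal); vectorised.
#' @param frame Frame index (1-based, 1 = end-diastole); vectorised.
#' @return Radius in mm.
#' @export
true_radius <- function(config, slice, frame) {
  if (any(slice < 1 | slice > config$n_slices)) stop("slice index out of range")
  if (any(frame < 1 | frame > config$n_frames)) stop("frame index out of range")
  z <- config$slice_offsets[slice]
  r0 <- config$base_radius * sqrt(pmax(0, 1 - (z / config$cap_half_height)^2))
  eps <- config$region_peak_strain[as.character(region_map(config$n_slices)[slice])]
  g <- (1 - cos(pi * (frame - 1) / (config$n_frames - 1))) / 2
  unname(r0 * (1 + eps * g))
}

#' Analytic phantom ground truth
#'
#' Per-slice, per-frame noise-free radius, circumference and enclosed area.
#'
#' @param config A [phantom_config()].
#' @return A tibble with columns `slice`, `frame`, `radius_mm`, `perimeter_cm`,
#'   `area_cm2`.
#' @export
phantom_truth <- function(config) {
  grid <- expand.grid(slice = seq_len(config$n_slices),
                      frame = seq_len(config$n_frames))
  r <- true_radius(config, grid$slice, grid$frame)
  tibble::tibble(slice = as.integer(grid$slice), frame = as.integer(grid$frame),
                 radius_mm = r,
                 perimeter_cm = 2 * pi * r / 10,
                 area_cm2 = pi * r^2 / 100) |>
    dplyr::arrange(.data$slice, .data$frame)
}

#' Analytic ground-truth clinical metrics
#'
#' Runs the standard metric chain ([clinical_metrics()]) on the exact analytic
#' perimeters and areas of the phantom, giving the reference ACS/MCS/BCS/GCS,
#' EDV/ESV and LVEF against which pipeline recoveries are judged.
#'
#' @param config A [phantom_config()].
#' @return A one-row tibble, see [clinical_metrics()].
#' @export
truth_metrics <- function(config) {
  clinical_metrics(phantom_truth(config),
                   slice_spacing = config$slice_spacing,
                   regions = region_map(config$n_slices))
}

# Deterministic substream seed for one contour. Successive multiplicative
# folds modulo 2^31 - 1; exact in double arithmetic (products < 2^53).
contour_seed <- function(seed, reader, repetition, software, slice, frame) {
  m <- 2147483647
  soft <- sum(utf8ToInt(as.character(software)) *
                seq_along(utf8ToInt(as.character(software)))) %% 99991
  h <- (abs(seed) %% m)
  for (k in c(reader, repetition, soft, slice, frame)) {
    h <- ((h * 48271) %% m + k + 1) %% m
  }
  as.integer(h)
}

# Evaluate code under a given seed without disturbing the caller's RNG state.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth zero-mean angular perturbation evaluated at the marker angles.
# Random Fourier coefficients over modes 1..M, rescaled so the angular RMS of
# the continuous field equals sd exactly.
angular_noise <- function(theta, sd, modes) {
  if (sd == 0) return(numeric(length(theta)))
  a <- stats::rnorm(modes)
  b <- stats::rnorm(modes)
  rms <- sqrt(sum(a^2 + b^2) / 2)
  if (rms == 0) return(numeric(length(theta)))
  phase <- outer(theta, seq_len(modes))
  as.vector((cos(phase) %*% a + sin(phase) %*% b) * sd / rms)
}

#' Render one simulated endocardial contour
#'
#' Places `n_markers` marker points at equally spaced angles (counter-clockwise,
#' closure implied) at radius `true_radius + reader noise + bias offset`, where
#' the software's length bias in cm is converted to the equivalent uniform
#' radial offset `bias * 10 / (2 * pi)` mm. The contour is centred on the mask
#' grid. Fully deterministic given `(seed, reader, repetition, software, slice,
#' frame)`.
#'
#' @param config A [phantom_config()].
#' @param slice,frame Stack indices (1-based).
#' @param reader Reader index (0 denotes the automated software's operator).
#' @param repetition Repetition index.
#' @param software Software label; must be one of the configured manual labels
#'   or the automated label.
#' @param noise_sd Radial noise SD in mm; defaults to the configured reader
#'   noise for manual software and 0 for the automated label.
#' @return An `n_markers x 2` matrix of (x, y) in mm with attributes `slice`
#'   and `frame`; class `contour_set`.
#' @export
render_contour <- function(config, slice, frame, reader = 1, repetition = 1,
                           software = names(config$software_length_bias)[1],
                           noise_sd = NULL) {
  automated <- identical(software, config$automated_label)
  if (!automated && !software %in% names(config$software_length_bias))
    stop("unknown software label: ", software)
  bias_cm <- if (automated) config$automated_length_bias
             else config$software_length_bias[[software]]
  if (is.null(noise_sd)) noise_sd <- if (automated) 0 else config$reader_noise_sd
  r <- true_radius(config, slice, frame)
  theta <- 2 * pi * (seq_len(config$n_markers) - 1) / config$n_markers
  delta <- if (noise_sd > 0) {
    with_rng_seed(
      contour_seed(config$seed, reader, repetition, software, slice, frame),
      angular_noise(theta, noise_sd, config$reader_noise_modes))
  } else numeric(length(theta))
  radius <- r + delta + bias_cm * 10 / (2 * pi)
  if (any(radius <= 0))
    stop(sprintf("non-positive contour radius at slice %d, frame %d", slice, frame))
  centre <- config$grid_size * config$pixel_spacing / 2
  pts <- cbind(x = centre + radius * cos(theta),
               y = centre + radius * sin(theta))
  structure(pts, slice = as.integer(slice), frame = as.integer(frame),
            class = c("contour_set", class(pts)))
}

# Even-odd point-in-polygon test, vectorised over query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / denom
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}

#' Rasterise a contour to a binary mask
#'
#' A pixel is foreground iff its centre lies strictly inside the closed polygon
#' through the contour points. Pixel centres sit at `(i - 1/2) * pixel_spacing`
#' for 1-based pixel index `i`, matching the hull convention in
#' [hull_perimeter()].
#'
#' @param contour A `contour_set` (points in mm) or a plain 2-column matrix.
#' @param config A [phantom_config()] supplying `grid_size` and `pixel_spacing`.
#' @return An integer `grid_size x grid_size` matrix of 0/1 with attribute
#'   `pixel_spacing`.
#' @export
rasterize_mask <- function(contour, config) {
  pts <- unclass(contour)
  extent <- config$grid_size * config$pixel_spacing
  if (any(pts < 0) || any(pts > extent))
    stop("contour escapes the mask grid")
  mask <- matrix(0L, config$grid_size, config$grid_size)
  ctr <- (seq_len(config$grid_size) - 0.5) * config$pixel_spacing
  ix <- which(ctr >= min(pts[, 1]) - config$pixel_spacing &
              ctr <= max(pts[, 1]) + config$pixel_spacing)
  iy <- which(ctr >= min(pts[, 2]) - config$pixel_spacing &
              ctr <= max(pts[, 2]) + config$pixel_spacing)
  if (length(ix) && length(iy)) {
    g <- expand.grid(ix = ix, iy = iy)
    inside <- points_in_polygon(ctr[g$ix], ctr[g$iy], pts[, 1], pts[, 2])
    mask[cbind(g$ix, g$iy)[inside, , drop = FALSE]] <- 1L
  }
  attr(mask, "pixel_spacing") <- config$pixel_spacing
  mask
}

#' Generate a full simulated multi-reader multi-software study
#'
#' Produces one manual-style session per (reader, software, repetition) plus
#' exactly one automated-style session (zero reader noise, single repetition),
#' each holding the rendered contours for every slice and frame, together with
#' the analytic ground truth. Reproducible bit-for-bit from the config seed.
#'
#' @param config A [phantom_config()].
#' @param software Manual software labels to generate (default all configured).
#' @param repetitions Repetition indices to generate (default all).
#' @param include_automated Generate the automated session?
#' @param include_masks Also rasterise every contour to a binary mask stack
#'   (stored per session as a 4-D x,y,slice,frame array)? Off by default; masks
#'   can always be regenerated per contour with [rasterize_mask()].
#' @return A list of class `lv_study` with elements `config`, `sessions` (list
#'   of session objects), and `truth` (list with `table` and `metrics`).
#' @export
generate_study <- function(config, software = names(config$software_length_bias),
                           repetitions = seq_len(config$n_repetitions),
                           include_automated = TRUE, include_masks = FALSE) {
  grid <- expand.grid(slice = seq_len(config$n_slices),
                      frame = seq_len(config$n_frames))
  make_session <- function(reader, soft, rep, type) {
    contours <- mapply(function(s, f) {
      render_contour(config, s, f, reader = reader, repetition = rep,
                     software = soft)
    }, grid$slice, grid$frame, SIMPLIFY = FALSE)
    session <- list(
      session_id = if (type == "manual")
        sprintf("%s_T%d_R%02d", soft, rep, reader) else sprintf("%s_auto", soft),
      reader = as.integer(reader), software = soft,
      repetition = as.integer(rep), type = type,
      contours = tibble::tibble(slice = as.integer(grid$slice),
                                frame = as.integer(grid$frame),
                                points = contours))
    if (include_masks) {
      masks <- array(0L, dim = c(config$grid_size, config$grid_size,
                                 config$n_slices, config$n_frames))
      for (k in seq_along(contours)) {
        masks[, , grid$slice[k], grid$frame[k]] <- rasterize_mask(contours[[k]], config)
      }
      session$masks <- masks
    }
    class(session) <- "lv_session"
    session
  }
  sessions <- list()
  for (soft in software)
    for (rep in repetitions)
      for (reader in seq_len(config$n_readers))
        sessions[[length(sessions) + 1L]] <- make_session(reader, soft, rep, "manual")
  if (include_automated)
    sessions[[length(sessions) + 1L]] <-
      make_session(0L, config$automated_label, 1L, "automated")
  names(sessions) <- vapply(sessions, `[[`, "", "session_id")
  structure(list(config = config, sessions = sessions,
                 truth = list(table = phantom_truth(config),
                              metrics = truth_metrics(config))),
            class = "lv_study")
}

#' @export
print.lv_study <- function(x, ...) {
  n_manual <- sum(vapply(x$sessions, function(s) s$type == "manual", TRUE))
  cat(sprintf("Simulated LV contouring study: %d manual + %d automated sessions\n",
              n_manual, length(x$sessions) - n_manual))
  cat(sprintf("  %d slices x %d frames, seed %d\n",
              x$config$n_slices, x$config$n_frames, x$config$seed))
  invisible(x)
}
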