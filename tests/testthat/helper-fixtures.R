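# Shared fixtures: small phantom configurations and hand-built sessions.

small_config <- function(seed = 123, ...) {
  phantom_config(n_frames = 4, n_readers = 2, grid_size = 64, seed = seed, ...)
}

noise_free_config <- function(...) {
  phantom_config(reader_noise_sd = 0,
                 software_length_bias = c(OsiriX = 0, ScanIP = -1.9),
                 seed = 123, ...)
}

# n equally spaced points on a circle, counter-clockwise, radius in mm.
circle_points <- function(n, radius, centre = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

# A synthetic session over an s x f grid with contours supplied by f(slice, frame).
manual_session <- function(n_slices, n_frames, contour_fun,
                           reader = 1, software = "A", repetition = 1) {
  grid <- expand.grid(slice = seq_len(n_slices), frame = seq_len(n_frames))
  structure(list(
    session_id = sprintf("%s_T%d_R%02d", software, repetition, reader),
    reader = reader, software = software, repetition = repetition,
    type = "manual",
    contours = tibble::tibble(
      slice = as.integer(grid$slice), frame = as.integer(grid$frame),
      points = mapply(contour_fun, grid$slice, grid$frame, SIMPLIFY = FALSE))),
    class = "lv_session")
}

# Measurement table for analytic per-slice radii r_mm[slice, frame].
radius_measurements <- function(r_mm) {
  grid <- expand.grid(slice = seq_len(nrow(r_mm)), frame = seq_len(ncol(r_mm)))
  r <- r_mm[cbind(grid$slice, grid$frame)]
  tibble::tibble(slice = as.integer(grid$slice), frame = as.integer(grid$frame),
                 perimeter_cm = 2 * pi * r / 10, area_cm2 = pi * r^2 / 100)
}
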