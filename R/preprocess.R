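#' Construct an RF frame
#'
#' Raw radiofrequency echo samples for one image plane: a matrix of real RF
#' values with axial samples in rows and scan lines in columns, plus the
#' acquisition geometry needed to place samples in mm.
#'
#' @param samples numeric matrix (axial x lateral) of RF values.
#' @param fs_hz sampling frequency (Hz).
#' @param line_pitch_mm lateral distance between scan lines (mm).
#' @param sound_speed_mps sound speed (m/s); the axial sample spacing is
#'   `sound_speed_mps * 1000 / (2 * fs_hz)` mm (pulse-echo round trip).
#' @return An `rf_frame` object.
#' @export
rf_frame <- function(samples, fs_hz, line_pitch_mm,
                     sound_speed_mps = 1540) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stopf("`samples` must be a numeric matrix")
  }
  if (ncol(samples) < 2L) stopf("an RF frame needs at least 2 scan lines")
  if (any(!is.finite(samples))) stopf("RF samples must be finite")
  check_scalar_pos(fs_hz, "fs_hz")
  check_scalar_pos(line_pitch_mm, "line_pitch_mm")
  check_scalar_pos(sound_speed_mps, "sound_speed_mps")
  structure(list(samples = samples, fs_hz = fs_hz,
                 line_pitch_mm = line_pitch_mm,
                 sound_speed_mps = sound_speed_mps,
                 sample_spacing_mm = sound_speed_mps * 1000 / (2 * fs_hz)),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines, fs %.1f MHz, pitch %.4f mm\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz / 1e6,
              x$line_pitch_mm))
  invisible(x)
}

envelope_image <- function(values, pixel_mm) {
  stopifnot(is.matrix(values), all(values >= 0), pixel_mm > 0)
  structure(list(values = values, pixel_mm = pixel_mm),
            class = "envelope_image")
}

bmode_image <- function(values_db, pixel_mm, db_range) {
  structure(list(values_db = values_db, pixel_mm = pixel_mm,
                 db_range = db_range),
            class = "bmode_image")
}

# Analytic-signal magnitude per column via the FFT (Hilbert transform).
analytic_envelope <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  X <- stats::mvfft(x) * h
  Mod(stats::mvfft(X, inverse = TRUE)) / n
}

#' Detect the signal envelope of an RF frame
#'
#' Computes the per-line analytic-signal magnitude (Hilbert demodulation)
#' and resamples it axially (linear interpolation) onto an isotropic pixel
#' grid with spacing `pixel_mm`, by default the line pitch, so that axial
#' and lateral pixel displacements are commensurate.
#'
#' @param rf an [rf_frame()].
#' @param pixel_mm target isotropic pixel spacing; default the line pitch.
#' @return An `envelope_image` (non-negative values, `pixel_mm` spacing).
#' @export
detect_envelope <- function(rf, pixel_mm = rf$line_pitch_mm) {
  stopifnot(inherits(rf, "rf_frame"))
  check_scalar_pos(pixel_mm, "pixel_mm")
  if (all(rf$samples == 0)) {
    warnf("RF frame is identically zero; returning a zero envelope")
    env <- rf$samples
  } else {
    env <- analytic_envelope(rf$samples)
  }
  dz <- rf$sample_spacing_mm
  nz <- nrow(env)
  depth_max <- (nz - 1L) * dz
  n_out <- floor(depth_max / pixel_mm) + 1L
  pos <- (seq_len(n_out) - 1L) * pixel_mm / dz
  i0 <- pmin(floor(pos) + 1L, nz - 1L)
  frac <- pos - (i0 - 1L)
  iso <- env[i0, , drop = FALSE] * (1 - frac) +
    env[i0 + 1L, , drop = FALSE] * frac
  iso[iso < 0] <- 0
  envelope_image(iso, pixel_mm)
}

#' Log-compress an envelope image to B-mode
#'
#' `values_db = 20 * log10(values / max(values)) + db_range[2]`, so the
#' frame maximum maps to the top of the dynamic range, then clipped to
#' `db_range`. The per-frame maximum is the dB reference because absolute
#' scanner gain is arbitrary; the window expresses relative dynamic range.
#'
#' @param env an `envelope_image`.
#' @param db_range two-element (low, high) display range in dB,
#'   default `c(20, 100)`.
#' @return A `bmode_image`.
#' @export
log_compress <- function(env, db_range = c(20, 100)) {
  stopifnot(inherits(env, "envelope_image"))
  if (length(db_range) != 2L || db_range[1L] >= db_range[2L]) {
    stopf("`db_range` must be (low, high) with low < high")
  }
  mx <- max(env$values)
  if (mx <= 0) stopf("cannot log-compress an all-zero envelope")
  vdb <- 20 * log10(env$values / mx) + db_range[2L]
  vdb[!is.finite(vdb)] <- db_range[1L]
  vdb <- pmin(pmax(vdb, db_range[1L]), db_range[2L])
  bmode_image(vdb, env$pixel_mm, db_range)
}

#' Estimate a depth-correction curve from a homogeneous phantom map
#'
#' From a parametric map of a statistically homogeneous reference phantom,
#' estimates one correction factor per map row (depth): the ratio of the
#' global map mean to the lateral row mean, smoothed with a centered
#' moving average over `smooth_rows` rows. Applying the curve flattens the
#' systematic depth dependence of the parameter. An additive variant
#' (offset = global mean - row mean) is also available.
#'
#' @param phantom_map a [parametric_map()] computed on a homogeneous
#'   phantom frame.
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @param smooth_rows moving-average width in rows (default 5).
#' @return A `correction_curve` (parameter, depth_mm, factor, mode).
#' @export
estimate_correction_curve <- function(phantom_map,
                                      mode = c("multiplicative", "additive"),
                                      smooth_rows = 5L) {
  stopifnot(inherits(phantom_map, "parametric_map"))
  mode <- match.arg(mode)
  vals <- phantom_map$values
  valid <- phantom_map$valid
  if (nrow(vals) < 2L) stopf("cannot smooth a single-row phantom map")
  row_mean <- vapply(seq_len(nrow(vals)), function(r) {
    v <- vals[r, valid[r, ]]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  if (any(!is.finite(row_mean))) stopf("phantom map has empty rows")
  global <- mean(vals[valid])
  if (mode == "multiplicative") {
    if (any(row_mean == 0)) stopf("zero row mean; cannot form factors")
    factor <- moving_average(global / row_mean, smooth_rows)
  } else {
    factor <- moving_average(global - row_mean, smooth_rows)
  }
  structure(list(parameter = phantom_map$parameter,
                 depth_mm = phantom_map$depth_mm,
                 factor = factor, mode = mode),
            class = "correction_curve")
}

#' Apply a depth-correction curve to a parametric map
#'
#' Multiplies (or offsets, for an additive curve) every map row by the
#' curve's factor at that depth. Parameter names and depth grids must
#' match; the validity mask is unchanged.
#'
#' @param map a [parametric_map()].
#' @param curve a `correction_curve` from [estimate_correction_curve()].
#' @return The corrected `parametric_map`.
#' @export
apply_correction <- function(map, curve) {
  stopifnot(inherits(map, "parametric_map"),
            inherits(curve, "correction_curve"))
  if (!identical(map$parameter, curve$parameter)) {
    stopf("parameter mismatch: map '%s' vs curve '%s'",
          map$parameter, curve$parameter)
  }
  if (length(map$depth_mm) != length(curve$depth_mm) ||
      max(abs(map$depth_mm - curve$depth_mm)) > 1e-9) {
    stopf("depth grid mismatch between map and correction curve")
  }
  map$values <- if (curve$mode == "multiplicative") {
    map$values * curve$factor
  } else {
    map$values + curve$factor
  }
  map
}
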