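#' Draw Nakagami-distributed envelope amplitudes
#'
#' Samples i.i.d. amplitudes from the Nakagami distribution with shape
#' parameter `nak` and mean power (second moment) `omega`. Internally the
#' squared amplitude is gamma-distributed with shape `nak` and scale
#' `omega / nak`, so `mean(A^2)` converges to `omega`. The special case
#' `nak = 1` is the Rayleigh envelope of fully developed speckle.
#'
#' @param n number of samples.
#' @param nak Nakagami shape parameter (> 0); < 1 pre-Rayleigh, > 1
#'   post-Rayleigh.
#' @param omega mean signal power (> 0).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return Numeric vector of `n` non-negative amplitudes.
#' @export
sample_nakagami_envelope <- function(n, nak, omega = 1, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stopf("`n` must be a positive count")
  }
  check_scalar_pos(nak, "nak")
  check_scalar_pos(omega, "omega")
  with_seed(seed, sqrt(rgamma(n, shape = nak, scale = omega / nak)))
}

#' Specify a synthetic ultrasound scene
#'
#' Describes a speckle scene: a uniform background, and optionally an
#' elliptical lesion with distinct envelope statistics in its interior and
#' in a surrounding rim band. The scene is the ground-truth world that
#' [make_speckle_rf()] realizes as an RF frame.
#'
#' Geometry is in mm with x lateral (across scan lines) and z axial (depth,
#' down). The RF grid has `grid_shape[1]` axial samples at the spacing
#' implied by `fs_hz` and `sound_speed_mps`, and `grid_shape[2]` scan lines
#' at `line_pitch_mm`. Defaults mirror a linear-array breast acquisition:
#' 40 MHz sampling, ~7.2 MHz carrier, 510 lines at 0.0745 mm pitch.
#'
#' @param grid_shape integer (axial_samples, lines).
#' @param fs_hz RF sampling frequency.
#' @param line_pitch_mm lateral distance between scan lines.
#' @param sound_speed_mps assumed sound speed (sets the axial sample spacing
#'   `sound_speed_mps * 1000 / (2 * fs_hz)` mm).
#' @param background_nak,background_omega Nakagami shape / mean power of the
#'   background speckle.
#' @param lesion_semi_axes_mm ellipse semi-axes (a_x, b_z) in mm, or `NULL`
#'   for a background-only scene.
#' @param lesion_center_mm ellipse centre (x, z) in mm; default grid centre.
#' @param lesion_rotation_deg ellipse rotation, degrees.
#' @param interior_nak,interior_omega envelope statistics inside the lesion.
#' @param rim_nak,rim_omega envelope statistics in the band of width
#'   `rim_width_mm` outside the lesion boundary.
#' @param rim_width_mm thickness of the rim band, mm.
#' @param carrier_hz carrier (centre) frequency of the imposed RF carrier.
#' @param cell_samples axial extent, in RF samples, of one resolution cell:
#'   envelope draw and carrier phase are held constant within a cell so that
#'   demodulation can recover the envelope statistics.
#' @param seed integer seed used when the scene is realized.
#' @return A `scene_spec` object (list).
#' @export
scene_spec <- function(grid_shape = c(1560L, 510L),
                       fs_hz = 40e6,
                       line_pitch_mm = 0.0745,
                       sound_speed_mps = 1540,
                       background_nak = 1, background_omega = 1,
                       lesion_semi_axes_mm = c(7, 5.8),
                       lesion_center_mm = NULL,
                       lesion_rotation_deg = 0,
                       interior_nak = 0.8, interior_omega = 0.45,
                       rim_nak = 1, rim_omega = 1,
                       rim_width_mm = 5,
                       carrier_hz = 7.2e6,
                       cell_samples = 3L,
                       seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    stopf("`grid_shape` must be two positive integers (axial, lines)")
  }
  check_scalar_pos(fs_hz, "fs_hz")
  check_scalar_pos(line_pitch_mm, "line_pitch_mm")
  check_scalar_pos(sound_speed_mps, "sound_speed_mps")
  check_scalar_pos(background_nak, "background_nak")
  check_scalar_pos(background_omega, "background_omega")
  check_scalar_pos(carrier_hz, "carrier_hz")
  if (cell_samples < 1L) stopf("`cell_samples` must be >= 1")
  sample_spacing_mm <- sound_speed_mps * 1000 / (2 * fs_hz)
  extent_mm <- c(grid_shape[1L] * sample_spacing_mm,
                 grid_shape[2L] * line_pitch_mm)  # (z, x)

  if (!is.null(lesion_semi_axes_mm)) {
    check_scalar_pos(interior_nak, "interior_nak")
    check_scalar_pos(interior_omega, "interior_omega")
    check_scalar_pos(rim_nak, "rim_nak")
    check_scalar_pos(rim_omega, "rim_omega")
    if (rim_width_mm < 0) stopf("`rim_width_mm` must be >= 0")
    if (length(lesion_semi_axes_mm) != 2L || any(lesion_semi_axes_mm <= 0)) {
      stopf("`lesion_semi_axes_mm` must be two positive numbers")
    }
    if (is.null(lesion_center_mm)) {
      lesion_center_mm <- c(extent_mm[2L] / 2, extent_mm[1L] / 2)
    }
    th <- lesion_rotation_deg * pi / 180
    a <- lesion_semi_axes_mm[1L]
    b <- lesion_semi_axes_mm[2L]
    half_x <- sqrt((a * cos(th))^2 + (b * sin(th))^2) + rim_width_mm
    half_z <- sqrt((a * sin(th))^2 + (b * cos(th))^2) + rim_width_mm
    if (lesion_center_mm[1L] - half_x < 0 ||
        lesion_center_mm[1L] + half_x > extent_mm[2L] ||
        lesion_center_mm[2L] - half_z < 0 ||
        lesion_center_mm[2L] + half_z > extent_mm[1L]) {
      stopf("lesion ellipse plus rim does not fit inside the grid")
    }
  }

  structure(list(
    grid_shape = grid_shape, fs_hz = fs_hz,
    line_pitch_mm = line_pitch_mm, sound_speed_mps = sound_speed_mps,
    sample_spacing_mm = sample_spacing_mm,
    background_nak = background_nak, background_omega = background_omega,
    lesion_semi_axes_mm = lesion_semi_axes_mm,
    lesion_center_mm = lesion_center_mm,
    lesion_rotation_deg = lesion_rotation_deg,
    interior_nak = interior_nak, interior_omega = interior_omega,
    rim_nak = rim_nak, rim_omega = rim_omega,
    rim_width_mm = rim_width_mm,
    carrier_hz = carrier_hz, cell_samples = as.integer(cell_samples),
    seed = seed
  ), class = "scene_spec")
}

#' Ground-truth region labels of a scene on an arbitrary grid
#'
#' Labels every pixel/sample centre as background (0), lesion interior (1)
#' or rim band (2). Rim membership uses the Euclidean distance transform of
#' the interior mask, i.e. the same geometric rule the ROI module applies.
#'
#' @param spec a [scene_spec()].
#' @param grid_shape (rows, cols) of the target grid.
#' @param row_spacing_mm,col_spacing_mm grid spacings; default the scene's
#'   RF sample spacing and line pitch.
#' @return Integer matrix of region codes.
#' @export
scene_region_ids <- function(spec, grid_shape = spec$grid_shape,
                             row_spacing_mm = spec$sample_spacing_mm,
                             col_spacing_mm = spec$line_pitch_mm) {
  nz <- grid_shape[1L]; nx <- grid_shape[2L]
  regions <- matrix(0L, nz, nx)
  if (is.null(spec$lesion_semi_axes_mm)) return(regions)
  zc <- (seq_len(nz) - 0.5) * row_spacing_mm
  xc <- (seq_len(nx) - 0.5) * col_spacing_mm
  z <- matrix(zc, nz, nx) - spec$lesion_center_mm[2L]
  x <- matrix(xc, nz, nx, byrow = TRUE) - spec$lesion_center_mm[1L]
  th <- spec$lesion_rotation_deg * pi / 180
  u <- x * cos(th) + z * sin(th)
  v <- -x * sin(th) + z * cos(th)
  interior <- (u / spec$lesion_semi_axes_mm[1L])^2 +
    (v / spec$lesion_semi_axes_mm[2L])^2 <= 1
  regions[interior] <- 1L
  if (spec$rim_width_mm > 0 && any(interior)) {
    d <- distance_to_mask(interior, row_spacing_mm, col_spacing_mm)
    regions[!interior & d <= spec$rim_width_mm] <- 2L
  }
  regions
}

# Region-wise Nakagami parameters as lookup vectors (bg, interior, rim).
scene_region_params <- function(spec) {
  list(nak = c(spec$background_nak, spec$interior_nak, spec$rim_nak),
       omega = c(spec$background_omega, spec$interior_omega, spec$rim_omega))
}

#' Realize a scene as a synthetic RF frame
#'
#' Draws one Nakagami envelope amplitude per resolution cell from the cell's
#' region law, holds it over `cell_samples` axial RF samples, and imposes a
#' carrier at the scene's centre frequency with a random phase per cell.
#' Envelope detection of the resulting frame recovers the per-region
#' envelope statistics within estimation tolerance.
#'
#' @param spec a [scene_spec()].
#' @return A list of class `qus_scene` with elements `frame`
#'   ([rf_frame()]), `regions` (ground-truth region codes on the RF grid)
#'   and `spec`.
#' @export
make_speckle_rf <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nz <- spec$grid_shape[1L]; nx <- spec$grid_shape[2L]
  if (nx < 2L) stopf("scene must have at least 2 scan lines")
  regions <- scene_region_ids(spec)
  pars <- scene_region_params(spec)

  cell <- spec$cell_samples
  n_cells <- ceiling(nz / cell)
  cell_of_row <- ((seq_len(nz) - 1L) %/% cell) + 1L
  centre_row <- pmin(nz, (seq_len(n_cells) - 1L) * cell + ceiling(cell / 2))
  reg_cell <- regions[centre_row, , drop = FALSE]

  rf <- with_seed(spec$seed, {
    nakv <- pars$nak[reg_cell + 1L]
    omegav <- pars$omega[reg_cell + 1L]
    amp_cell <- matrix(sqrt(rgamma(n_cells * nx, shape = nakv,
                                   scale = omegav / nakv)), n_cells, nx)
    phase_cell <- matrix(runif(n_cells * nx, 0, 2 * pi), n_cells, nx)
    amp <- amp_cell[cell_of_row, , drop = FALSE]
    phase <- phase_cell[cell_of_row, , drop = FALSE]
    w <- 2 * pi * spec$carrier_hz / spec$fs_hz
    amp * cos(w * (seq_len(nz) - 1L) + phase)
  })

  structure(list(
    frame = rf_frame(rf, fs_hz = spec$fs_hz,
                     line_pitch_mm = spec$line_pitch_mm,
                     sound_speed_mps = spec$sound_speed_mps),
    regions = regions,
    spec = spec
  ), class = "qus_scene")
}

#' Generate a homogeneous reference-phantom RF frame
#'
#' A statistically homogeneous speckle frame (uniform Nakagami law) with an
#' imposed multiplicative depth-dependent amplitude gain, emulating the
#' system/beam depth bias that reference-phantom correction curves are
#' estimated from and meant to remove.
#'
#' @param grid_shape (axial_samples, lines).
#' @param nak,omega envelope statistics of the phantom speckle.
#' @param depth_gain scalar, vector of length `grid_shape[1]`, or a
#'   function of depth (mm) returning the multiplicative amplitude gain;
#'   must be strictly positive.
#' @param seed integer seed.
#' @inheritParams scene_spec
#' @return An [rf_frame()].
#' @export
make_reference_phantom <- function(grid_shape = c(1560L, 510L),
                                   nak = 1, omega = 1, depth_gain = 1,
                                   fs_hz = 40e6, line_pitch_mm = 0.0745,
                                   sound_speed_mps = 1540,
                                   carrier_hz = 7.2e6, cell_samples = 3L,
                                   seed = NULL) {
  spec <- scene_spec(grid_shape = grid_shape, fs_hz = fs_hz,
                     line_pitch_mm = line_pitch_mm,
                     sound_speed_mps = sound_speed_mps,
                     background_nak = nak, background_omega = omega,
                     lesion_semi_axes_mm = NULL,
                     carrier_hz = carrier_hz, cell_samples = cell_samples,
                     seed = seed)
  nz <- spec$grid_shape[1L]
  depth <- (seq_len(nz) - 0.5) * spec$sample_spacing_mm
  gain <- if (is.function(depth_gain)) {
    depth_gain(depth)
  } else if (length(depth_gain) == 1L) {
    rep(depth_gain, nz)
  } else {
    depth_gain
  }
  if (length(gain) != nz || any(!is.finite(gain)) || any(gain <= 0)) {
    stopf("`depth_gain` must be strictly positive at every depth")
  }
  scene <- make_speckle_rf(spec)
  rf <- scene$frame$samples * gain
  rf_frame(rf, fs_hz = spec$fs_hz, line_pitch_mm = spec$line_pitch_mm,
           sound_speed_mps = spec$sound_speed_mps)
}

#' Specify a synthetic lesion cohort
#'
#' A cohort is a set of benign and malignant lesions, each scanned in two
#' planes (emulating longitudinal and transverse sweeps), with per-lesion
#' jitter of geometry and envelope statistics around the class template.
#'
#' @param n_benign,n_malignant lesion counts (>= 1).
#' @param benign_scene,malignant_scene [scene_spec()] class templates.
#' @param planes_per_lesion fixed at 2.
#' @param per_lesion_jitter relative half-width of the uniform jitter
#'   applied to lesion geometry and region statistics across lesions.
#' @param seed integer seed for the whole cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_benign = 59L, n_malignant = 57L,
                        benign_scene = scene_spec(),
                        malignant_scene = scene_spec(rim_nak = 0.7,
                                                     rim_omega = 1.25),
                        planes_per_lesion = 2L,
                        per_lesion_jitter = 0.1,
                        seed = 1L) {
  if (n_benign < 1L || n_malignant < 1L) stopf("class counts must be >= 1")
  if (planes_per_lesion != 2L) stopf("`planes_per_lesion` is fixed at 2")
  stopifnot(inherits(benign_scene, "scene_spec"),
            inherits(malignant_scene, "scene_spec"))
  if (per_lesion_jitter < 0 || per_lesion_jitter >= 1) {
    stopf("`per_lesion_jitter` must be in [0, 1)")
  }
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 benign_scene = benign_scene,
                 malignant_scene = malignant_scene,
                 planes_per_lesion = 2L,
                 per_lesion_jitter = per_lesion_jitter,
                 seed = seed),
            class = "cohort_spec")
}

#' Preset cohort specifications with a localized class effect
#'
#' Convenience constructor for the two simulation worlds used to probe
#' where class information lives: `"rim"` places the benign/malignant
#' difference only in the peritumoral rim statistics (interiors
#' identically distributed), `"interior"` places it only inside the lesion
#' (rims identical), `"none"` makes the classes exchangeable.
#'
#' `reduced = TRUE` shrinks the scene (smaller grid and lesion) so that a
#' full 116-lesion cohort stays affordable; the statistical structure is
#' unchanged.
#'
#' @param effect where the class effect lives.
#' @param n_benign,n_malignant lesion counts.
#' @param seed cohort seed.
#' @param reduced use the reduced-scale scene (default) or the full-size
#'   acquisition grid.
#' @return A [cohort_spec()].
#' @export
cohort_preset <- function(effect = c("rim", "interior", "none"),
                          n_benign = 59L, n_malignant = 57L,
                          seed = 1L, reduced = TRUE) {
  effect <- match.arg(effect)
  base <- if (reduced) {
    list(grid_shape = c(912L, 240L), lesion_semi_axes_mm = c(2.8, 2.3))
  } else {
    list(grid_shape = c(1560L, 510L), lesion_semi_axes_mm = c(7, 5.8))
  }
  mk <- function(...) {
    do.call(scene_spec, c(base, list(...)))
  }
  benign <- mk()
  malignant <- switch(effect,
    rim = mk(rim_nak = 0.7, rim_omega = 1.25),
    interior = mk(interior_nak = 0.55, interior_omega = 0.6),
    none = mk())
  cohort_spec(n_benign = n_benign, n_malignant = n_malignant,
              benign_scene = benign, malignant_scene = malignant,
              seed = seed)
}

#' 64-vertex closed polygon tracing an ellipse
#'
#' @param center_mm (x, z) centre.
#' @param semi_axes_mm (a, b) semi-axes.
#' @param rotation_deg rotation.
#' @param n_vertices number of distinct vertices; the first vertex is
#'   repeated at the end to close the ring.
#' @return `(n_vertices + 1) x 2` matrix with columns x_mm, z_mm.
#' @export
ellipse_polygon <- function(center_mm, semi_axes_mm, rotation_deg = 0,
                            n_vertices = 64L) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  th <- rotation_deg * pi / 180
  u <- semi_axes_mm[1L] * cos(t)
  v <- semi_axes_mm[2L] * sin(t)
  x <- center_mm[1L] + u * cos(th) - v * sin(th)
  z <- center_mm[2L] + u * sin(th) + v * cos(th)
  poly <- cbind(x_mm = c(x, x[1L]), z_mm = c(z, z[1L]))
  poly
}

#' Generate a synthetic lesion cohort
#'
#' Realizes a [cohort_spec()]: per lesion, the class template is jittered
#' (geometry, rotation and region statistics), the same lesion is imaged in
#' two independent speckle realizations (the two scan planes), and the true
#' ellipse is emitted as a closed 64-vertex contour polygon.
#'
#' @param spec a [cohort_spec()].
#' @param materialize if `TRUE`, RF frames are generated now and stored in
#'   the bundle; if `FALSE` (memory-friendly), only the per-plane scene
#'   specs (with their seeds) are stored and frames are generated on demand
#'   by [lesion_frames()]. Both modes are bit-reproducible for a fixed seed.
#' @return A list of class `qus_cohort` with elements `lesions` (list of
#'   per-lesion bundles: `lesion_id`, `label`, `contour`, `scenes`, and
#'   `frames` when materialized) and `labels` (data frame lesion_id, label).
#' @export
make_cohort <- function(spec, materialize = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_benign + spec$n_malignant
  labels <- c(rep("benign", spec$n_benign),
              rep("malignant", spec$n_malignant))
  jit <- spec$per_lesion_jitter

  lesions <- with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      tmpl <- if (labels[i] == "benign") spec$benign_scene else
        spec$malignant_scene
      jf <- function(v) v * (1 + jit * runif(length(v), -1, 1))
      semi <- jf(tmpl$lesion_semi_axes_mm)
      rot <- tmpl$lesion_rotation_deg + runif(1, -20, 20)
      stat <- list(background_nak = jf(tmpl$background_nak),
                   background_omega = jf(tmpl$background_omega),
                   interior_nak = jf(tmpl$interior_nak),
                   interior_omega = jf(tmpl$interior_omega),
                   rim_nak = jf(tmpl$rim_nak),
                   rim_omega = jf(tmpl$rim_omega))
      plane_seeds <- sample.int(.Machine$integer.max, 2L)
      scenes <- lapply(plane_seeds, function(s) {
        scene_spec(grid_shape = tmpl$grid_shape, fs_hz = tmpl$fs_hz,
                   line_pitch_mm = tmpl$line_pitch_mm,
                   sound_speed_mps = tmpl$sound_speed_mps,
                   background_nak = stat$background_nak,
                   background_omega = stat$background_omega,
                   lesion_semi_axes_mm = semi,
                   lesion_center_mm = tmpl$lesion_center_mm,
                   lesion_rotation_deg = rot,
                   interior_nak = stat$interior_nak,
                   interior_omega = stat$interior_omega,
                   rim_nak = stat$rim_nak, rim_omega = stat$rim_omega,
                   rim_width_mm = tmpl$rim_width_mm,
                   carrier_hz = tmpl$carrier_hz,
                   cell_samples = tmpl$cell_samples, seed = s)
      })
      sc1 <- scenes[[1L]]
      contour <- ellipse_polygon(sc1$lesion_center_mm,
                                 sc1$lesion_semi_axes_mm,
                                 sc1$lesion_rotation_deg)
      out <- list(lesion_id = sprintf("L%03d", i), label = labels[i],
                  contour = contour, scenes = scenes)
      if (materialize) {
        out$frames <- lapply(scenes, function(s) make_speckle_rf(s)$frame)
      }
      out
    })
  })

  structure(list(
    lesions = lesions,
    labels = data.frame(lesion_id = vapply(lesions, `[[`, "", "lesion_id"),
                        label = labels, stringsAsFactors = FALSE),
    spec = spec
  ), class = "qus_cohort")
}

#' RF frames of one cohort lesion
#'
#' Returns the lesion's two plane frames, generating them from the stored
#' per-plane scene specs if the cohort was not materialized.
#'
#' @param cohort a `qus_cohort`.
#' @param i lesion index.
#' @return List of two [rf_frame()] objects.
#' @export
lesion_frames <- function(cohort, i) {
  les <- cohort$lesions[[i]]
  if (!is.null(les$frames)) return(les$frames)
  lapply(les$scenes, function(s) make_speckle_rf(s)$frame)
}

#' @export
print.qus_cohort <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<qus_cohort> %d lesions (%s), %d planes each\n",
              nrow(x$labels),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$spec$planes_per_lesion))
  invisible(x)
}
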