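#' Nakagami shape parameter by the method of moments
#'
#' `NAK = mean(A^2)^2 / var(A^2)` with the population variance
#' (denominator n). The estimator is exactly scale-invariant; NAK ~ 1 for
#' fully developed (Rayleigh) speckle, < 1 pre-Rayleigh, > 1 post-Rayleigh.
#'
#' @param amplitudes non-negative envelope amplitudes from one window.
#' @return The shape-parameter estimate, or `NA` for a degenerate
#'   (constant or too small) block.
#' @export
nakagami_mom <- function(amplitudes) {
  if (length(amplitudes) < 2L) return(NA_real_)
  a2 <- amplitudes * amplitudes
  m <- mean(a2)
  v <- mean((a2 - m)^2)
  if (v == 0) return(NA_real_)
  m * m / v
}

#' Weighted entropy of an envelope block
#'
#' `ENT = -sum_i w(A_i) P(A_i) log2 P(A_i)` over the block's samples, with
#' weights `w(A_i) = A_i / sum(A)` and `P(A_i)` the histogram-estimated
#' probability of the bin containing `A_i` (`n_bins` equal-width bins
#' spanning the block's range). A constant block occupies one bin with
#' probability 1 and has zero entropy.
#'
#' @param amplitudes envelope amplitudes from one window.
#' @param n_bins number of histogram bins (default 40).
#' @return The entropy value (>= 0), or `NA` for a degenerate block.
#' @export
weighted_entropy <- function(amplitudes, n_bins = 40L) {
  n <- length(amplitudes)
  if (n < 2L) return(NA_real_)
  s <- sum(amplitudes)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  lo <- min(amplitudes); hi <- max(amplitudes)
  if (hi == lo) return(0)
  bin <- pmin(floor((amplitudes - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, n_bins) / n
  pi_ <- p[bin]
  -sum(amplitudes / s * pi_ * log2(pi_))
}

# Quantize B-mode dB values into `levels` equal bins over db_range,
# top-edge values in the top bin.
quantize_db <- function(values_db, levels = 20L, db_range = c(20, 100)) {
  q <- floor((values_db - db_range[1L]) / diff(db_range) * levels) + 1L
  q[q < 1L] <- 1L
  q[q > levels] <- levels
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix of an image block
#'
#' Counts ordered pairs of quantized gray levels at a fixed displacement —
#' `"vertical"` pairs a pixel with the one `displacement_px` rows below,
#' `"horizontal"` with the one `displacement_px` columns to the right — and
#' normalizes so the matrix sums to 1. Pairs are not symmetrized: one
#' displacement per direction.
#'
#' @param block numeric matrix of B-mode dB values (or pre-quantized
#'   integers if `quantized = TRUE`).
#' @param direction `"vertical"` or `"horizontal"`.
#' @param displacement_px pixel displacement (default 4, i.e. 0.3 mm at
#'   0.075 mm pitch).
#' @param levels number of gray levels (default 20).
#' @param db_range dynamic range used for quantization.
#' @param quantized set `TRUE` if `block` already holds levels `1..levels`.
#' @return A `levels x levels` matrix of pair probabilities, or `NULL` if
#'   the block is too small for the displacement.
#' @export
compute_glcm <- function(block, direction = c("vertical", "horizontal"),
                         displacement_px = 4L, levels = 20L,
                         db_range = c(20, 100), quantized = FALSE) {
  direction <- match.arg(direction)
  d <- as.integer(displacement_px)
  if (d < 1L) stopf("`displacement_px` must be >= 1")
  nr <- nrow(block); nc <- ncol(block)
  if ((direction == "vertical" && nr <= d) ||
      (direction == "horizontal" && nc <= d)) {
    return(NULL)
  }
  q <- if (quantized) block else quantize_db(block, levels, db_range)
  if (direction == "vertical") {
    from <- q[seq_len(nr - d), , drop = FALSE]
    to <- q[(d + 1L):nr, , drop = FALSE]
  } else {
    from <- q[, seq_len(nc - d), drop = FALSE]
    to <- q[, (d + 1L):nc, drop = FALSE]
  }
  counts <- tabulate((from - 1L) * levels + to, nbins = levels * levels)
  g <- matrix(counts / sum(counts), levels, levels, byrow = TRUE)
  g
}

#' Haralick features of a normalized GLCM
#'
#' Contrast, correlation, energy, homogeneity and variance:
#' `CON = sum |i-j|^2 g`, `COR = sum (i-mu_i)(j-mu_j) g / (sigma_i sigma_j)`,
#' `ENE = sum g^2`, `HOM = sum g / (1 + |i-j|^2)`,
#' `VAR = sum (i-mu_i)^2 g`, with `mu`/`sigma` the marginal means and SDs
#' of the row (i) and column (j) level indices. `COR` is `NA` when a
#' marginal SD is zero (e.g. a constant block).
#'
#' @param g normalized GLCM (sums to 1).
#' @return Named numeric vector `CON`, `COR`, `ENE`, `HOM`, `VAR`.
#' @export
glcm_features <- function(g) {
  L <- nrow(g)
  idx <- seq_len(L)
  pi_ <- rowSums(g)
  pj_ <- colSums(g)
  mui <- sum(idx * pi_)
  muj <- sum(idx * pj_)
  sdi <- sqrt(sum((idx - mui)^2 * pi_))
  sdj <- sqrt(sum((idx - muj)^2 * pj_))
  dif2 <- outer(idx, idx, function(i, j) (i - j)^2)
  con <- sum(dif2 * g)
  ene <- sum(g * g)
  hom <- sum(g / (1 + dif2))
  varr <- sum((idx - mui)^2 * pi_)
  cor <- if (sdi == 0 || sdj == 0) {
    NA_real_
  } else {
    (sum(outer(idx, idx) * g) - mui * muj) / (sdi * sdj)
  }
  c(CON = con, COR = cor, ENE = ene, HOM = hom, VAR = varr)
}

#' Construct a parametric map container
#'
#' Per-window parameter values on the window-centre grid, with a validity
#' mask (estimation succeeded) and the depth coordinate of each row.
#'
#' @param parameter one of [qus_parameters()].
#' @param values numeric matrix (axial placements x lateral placements).
#' @param valid logical matrix, same shape.
#' @param depth_mm depth (mm) of each placement row's window centre.
#' @param pixel_mm pixel spacing of the underlying image.
#' @return A `parametric_map`.
#' @export
parametric_map <- function(parameter, values, valid, depth_mm, pixel_mm) {
  stopifnot(parameter %in% QUS_PARAMS, is.matrix(values),
            identical(dim(values), dim(valid)),
            length(depth_mm) == nrow(values))
  structure(list(parameter = parameter, values = values, valid = valid,
                 depth_mm = depth_mm, pixel_mm = pixel_mm),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s, %d x %d windows (%d valid)\n",
              x$parameter, nrow(x$values), ncol(x$values), sum(x$valid)))
  invisible(x)
}

# Dispatch one estimator on one pixel block.
estimate_window <- function(parameter, block, entropy_bins,
                            displacement_px, levels) {
  if (parameter == "NAK") return(nakagami_mom(as.vector(block)))
  if (parameter == "ENT") return(weighted_entropy(as.vector(block),
                                                  entropy_bins))
  feat <- substr(parameter, 1L, 3L)
  dirn <- if (substr(parameter, 4L, 4L) == "V") "vertical" else "horizontal"
  g <- compute_glcm(block, dirn, displacement_px, levels, quantized = TRUE)
  if (is.null(g)) return(NA_real_)
  unname(glcm_features(g)[feat])
}

#' Build a parametric map with the sliding-window technique
#'
#' Evaluates one of the twelve QUS estimators on the block of image data
#' under every window placement. `NAK` and `ENT` consume envelope blocks;
#' the texture features consume log-compressed B-mode blocks. Windows
#' where estimation fails (degenerate block, insufficient extent for the
#' GLCM displacement) are marked invalid. An optional reference-phantom
#' correction curve is applied to the finished map.
#'
#' @param image an `envelope_image` (for `NAK`, `ENT`) or `bmode_image`
#'   (texture parameters).
#' @param windows a [place_windows()] grid on the image's pixel grid.
#' @param parameter one of [qus_parameters()].
#' @param correction optional `correction_curve`.
#' @param placements optional data frame (as from [assign_windows()])
#'   restricting computation to those placements; other windows stay
#'   invalid. Saves work when only ROI windows are needed.
#' @param entropy_bins histogram bins for `ENT` (default 40).
#' @param displacement_mm GLCM displacement (default 0.3 mm).
#' @param levels GLCM gray levels (default 20).
#' @return A [parametric_map()].
#' @export
build_parametric_map <- function(image, windows, parameter,
                                 correction = NULL, placements = NULL,
                                 entropy_bins = 40L, displacement_mm = 0.3,
                                 levels = 20L) {
  if (!parameter %in% QUS_PARAMS) {
    stopf("unknown parameter '%s'", parameter)
  }
  is_texture <- !parameter %in% c("NAK", "ENT")
  if (is_texture) {
    stopifnot(inherits(image, "bmode_image"))
    vals <- quantize_db(image$values_db, levels, image$db_range)
  } else {
    stopifnot(inherits(image, "envelope_image"))
    vals <- image$values
  }
  stopifnot(identical(as.integer(dim(vals)),
                      as.integer(windows$grid_shape)))
  displacement_px <- max(1L, as.integer(round(displacement_mm /
                                                windows$pixel_mm)))
  wp <- windows$window_px
  na <- length(windows$row_start); nl <- length(windows$col_start)
  out <- matrix(NA_real_, na, nl)
  if (is.null(placements)) {
    placements <- data.frame(
      ai = rep(seq_len(na), times = nl),
      li = rep(seq_len(nl), each = na),
      row = rep(windows$row_start, times = nl),
      col = rep(windows$col_start, each = na))
  }
  for (q in seq_len(nrow(placements))) {
    r0 <- placements$row[q]; c0 <- placements$col[q]
    block <- vals[r0:(r0 + wp - 1L), c0:(c0 + wp - 1L)]
    out[placements$ai[q], placements$li[q]] <-
      estimate_window(parameter, block, entropy_bins, displacement_px,
                      levels)
  }
  valid <- !is.na(out)
  if (!any(valid)) stopf("no valid windows for parameter %s", parameter)
  ctr <- window_centers(windows)
  depth_mm <- (ctr$row - 0.5) * windows$pixel_mm
  map <- parametric_map(parameter, out, valid, depth_mm, windows$pixel_mm)
  if (!is.null(correction)) map <- apply_correction(map, correction)
  map
}

#' Build all twelve parametric maps in one pass
#'
#' Fast engine evaluating every QUS parameter on every (or a restricted
#' set of) window placement(s) in a single sweep over the image data.
#' Identical estimators to [build_parametric_map()] (which is the
#' readable single-parameter route); the two are cross-checked in the
#' test suite.
#'
#' @param env an `envelope_image`.
#' @param bm the matching `bmode_image` (same grid).
#' @param windows a [place_windows()] grid.
#' @param placements optional restriction (as from [assign_windows()]).
#' @param corrections optional named list of `correction_curve`s.
#' @inheritParams build_parametric_map
#' @return Named list of twelve [parametric_map()]s.
#' @export
build_parametric_maps <- function(env, bm, windows, placements = NULL,
                                  corrections = NULL, entropy_bins = 40L,
                                  displacement_mm = 0.3, levels = 20L) {
  stopifnot(inherits(env, "envelope_image"), inherits(bm, "bmode_image"))
  quant <- quantize_db(bm$values_db, levels, bm$db_range)
  na <- length(windows$row_start); nl <- length(windows$col_start)
  if (is.null(placements)) {
    placements <- data.frame(
      ai = rep(seq_len(na), times = nl),
      li = rep(seq_len(nl), each = na),
      row = rep(windows$row_start, times = nl),
      col = rep(windows$col_start, each = na))
  }
  displacement_px <- max(1L, as.integer(round(displacement_mm /
                                                windows$pixel_mm)))
  vals <- .qus_maps_cpp(env$values, quant, as.integer(placements$row),
                        as.integer(placements$col), windows$window_px,
                        as.integer(entropy_bins), displacement_px,
                        as.integer(levels))
  ctr <- window_centers(windows)
  depth_mm <- (ctr$row - 0.5) * windows$pixel_mm
  idx <- cbind(placements$ai, placements$li)
  maps <- lapply(seq_along(QUS_PARAMS), function(p) {
    m <- matrix(NA_real_, na, nl)
    m[idx] <- vals[, p]
    map <- parametric_map(QUS_PARAMS[p], m, !is.na(m), depth_mm,
                          windows$pixel_mm)
    crv <- corrections[[QUS_PARAMS[p]]]
    if (!is.null(crv)) map <- apply_correction(map, crv)
    map
  })
  stats::setNames(maps, QUS_PARAMS)
}

#' ROI-averaged parameter value across scan planes
#'
#' Pools the valid in-ROI window values of the parametric maps from all
#' planes and returns their unweighted mean.
#'
#' @param maps list of [parametric_map()]s, one per plane.
#' @param assignments list of window-assignment data frames (from
#'   [assign_windows()]), parallel to `maps`.
#' @return Scalar mean, or `NA` if no valid in-ROI window exists.
#' @export
roi_average <- function(maps, assignments) {
  stopifnot(length(maps) == length(assignments))
  vals <- unlist(lapply(seq_along(maps), function(p) {
    m <- maps[[p]]; a <- assignments[[p]]
    idx <- cbind(a$ai, a$li)
    v <- m$values[idx]
    v[m$valid[idx]]
  }))
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Extract the per-lesion feature table from a cohort
#'
#' Runs the full per-lesion chain — envelope detection, log compression,
#' internal/external ROI construction, sliding-window parametric maps for
#' the twelve QUS parameters, optional phantom correction, and ROI
#' averaging pooled over the two scan planes — and returns one row per
#' lesion with 24 features (12 parameters x internal/external). Lesions
#' with any missing feature (e.g. an empty ROI) are dropped with a message.
#'
#' @param cohort a `qus_cohort` from [make_cohort()], or a compatible list
#'   with `lesions` (each having `lesion_id`, `label`, `contour`, and
#'   either `frames` or `scenes`).
#' @param window_mm,overlap sliding-window size and overlap.
#' @param rim_width_mm external rim width (default 5 mm).
#' @param db_range,levels,displacement_mm,entropy_bins estimator settings.
#' @param correction optional named list of `correction_curve`s (one per
#'   parameter) from a reference phantom.
#' @param exclusions optional list of exclusion masks applied to the rim.
#' @param verbose print a progress message per lesion.
#' @return Data frame: `lesion_id`, `label`, then `NAK_int` ... `VARH_int`,
#'   `NAK_ext` ... `VARH_ext`.
#' @export
extract_features <- function(cohort, window_mm = 1, overlap = 0.92,
                             rim_width_mm = 5, db_range = c(20, 100),
                             levels = 20L, displacement_mm = 0.3,
                             entropy_bins = 40L, correction = NULL,
                             exclusions = NULL, verbose = FALSE) {
  lesions <- cohort$lesions
  cols <- c(paste0(QUS_PARAMS, "_int"), paste0(QUS_PARAMS, "_ext"))
  rows <- vector("list", length(lesions))
  dropped <- character(0)

  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    frames <- if (!is.null(les$frames)) les$frames else
      lapply(les$scenes, function(s) make_speckle_rf(s)$frame)
    maps_by_plane <- vector("list", length(frames))
    asg_int <- vector("list", length(frames))
    asg_ext <- vector("list", length(frames))
    geom <- NULL  # ROI geometry reused across planes with equal grids
    ok <- TRUE
    for (p in seq_along(frames)) {
      env <- detect_envelope(frames[[p]])
      bm <- log_compress(env, db_range)
      gs <- dim(env$values)
      if (is.null(geom) || !identical(geom$gs, gs)) {
        internal <- rasterize_contour(les$contour, gs, env$pixel_mm,
                                      contour_id = les$lesion_id)
        if (!any(internal$mask)) { ok <- FALSE; break }
        external <- external_rim(internal, rim_width_mm, exclusions)
        windows <- place_windows(gs, env$pixel_mm, window_mm, overlap)
        ai <- assign_windows(windows, internal)
        ae <- assign_windows(windows, external)
        geom <- list(gs = gs, windows = windows, ai = ai, ae = ae)
      }
      if (nrow(geom$ai) == 0L || nrow(geom$ae) == 0L) { ok <- FALSE; break }
      both <- rbind(geom$ai, geom$ae)
      maps_by_plane[[p]] <- build_parametric_maps(
        env, bm, geom$windows, placements = both,
        corrections = correction, entropy_bins = entropy_bins,
        displacement_mm = displacement_mm, levels = levels)
      asg_int[[p]] <- geom$ai
      asg_ext[[p]] <- geom$ae
    }
    if (!ok) {
      dropped <- c(dropped, les$lesion_id)
      next
    }
    vals <- c(
      vapply(QUS_PARAMS, function(pp) {
        roi_average(lapply(maps_by_plane, `[[`, pp), asg_int)
      }, numeric(1)),
      vapply(QUS_PARAMS, function(pp) {
        roi_average(lapply(maps_by_plane, `[[`, pp), asg_ext)
      }, numeric(1)))
    if (any(!is.finite(vals))) {
      dropped <- c(dropped, les$lesion_id)
      next
    }
    row <- as.data.frame(as.list(vals))
    names(row) <- cols
    row <- cbind(data.frame(lesion_id = les$lesion_id, label = les$label,
                            stringsAsFactors = FALSE), row)
    rows[[i]] <- row
    if (verbose) message(sprintf("extracted %s (%s)", les$lesion_id,
                                 les$label))
  }
  if (length(dropped) > 0L) {
    message(sprintf("dropped %d lesion(s) with missing features: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
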