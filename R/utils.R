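stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

# Run `expr` with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards so generators are reproducible without side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Centered moving average with window truncation at the edges.
moving_average <- function(x, width) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Euclidean distance (mm) from every pixel to the nearest TRUE pixel.
distance_to_mask <- function(mask, row_spacing, col_spacing = row_spacing) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .dist_transform_cpp(mask, row_spacing, col_spacing)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# `poly` is an open ring (first vertex not repeated), columns x, z.
points_in_polygon <- function(px, pz, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1L]; zi <- poly[i, 2L]
    xj <- poly[j, 1L]; zj <- poly[j, 2L]
    crosses <- ((zi > pz) != (zj > pz)) &
      (px < (xj - xi) * (pz - zi) / (zj - zi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

seg_orient <- function(ax, az, bx, bz, cx, cz) {
  v <- (bx - ax) * (cz - az) - (bz - az) * (cx - ax)
  if (abs(v) < 1e-12) 0 else sign(v)
}

segments_cross <- function(p1, p2, p3, p4) {
  o1 <- seg_orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  o2 <- seg_orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  o3 <- seg_orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  o4 <- seg_orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (o1 == 0 && on_seg(p1, p2, p3)) || (o2 == 0 && on_seg(p1, p2, p4)) ||
    (o3 == 0 && on_seg(p3, p4, p1)) || (o4 == 0 && on_seg(p3, p4, p2))
}

# TRUE if the closed ring defined by `poly` (open ring matrix) has any two
# non-adjacent edges intersecting. Proper crossings are detected with
# vectorized orientation tests; the rare degenerate pairs (an orientation
# of zero) fall back to the exact scalar routine.
polygon_self_intersects <- function(poly) {
  nv <- nrow(poly)
  x1 <- poly[, 1L]; z1 <- poly[, 2L]
  nxt <- c(seq_len(nv)[-1L], 1L)
  x2 <- x1[nxt]; z2 <- z1[nxt]
  dx <- x2 - x1; dz <- z2 - z1
  # o1[a,b] = orientation of edge a's direction w.r.t. start of edge b, etc.
  o1 <- (outer(dx, z1) - dx * z1) - (outer(dz, x1) - dz * x1)
  o2 <- (outer(dx, z2) - dx * z1) - (outer(dz, x2) - dz * x1)
  o3 <- t(o1)
  o4 <- t(o2)
  adjacent <- abs(outer(seq_len(nv), seq_len(nv), `-`)) %in% c(0L, 1L, nv - 1L)
  eps <- 1e-12
  proper <- (o1 * o2 < -eps) & (o3 * o4 < -eps) & !adjacent
  if (any(proper)) return(TRUE)
  degen <- (abs(o1) <= eps | abs(o2) <= eps | abs(o3) <= eps |
              abs(o4) <= eps) & !adjacent
  if (any(degen)) {
    for (idx in which(degen & upper.tri(degen))) {
      a <- (idx - 1L) %% nv + 1L
      b <- (idx - 1L) %/% nv + 1L
      if (segments_cross(c(x1[a], z1[a]), c(x2[a], z2[a]),
                         c(x1[b], z1[b]), c(x2[b], z2[b]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Content hash of an R object via its serialization, for stage caching.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}
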