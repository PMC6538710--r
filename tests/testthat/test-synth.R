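test_that("sample_nakagami_envelope rejects invalid parameters", {
  expect_error(sample_nakagami_envelope(10, nak = 0), "nak")
  expect_error(sample_nakagami_envelope(10, nak = -1), "nak")
  expect_error(sample_nakagami_envelope(10, nak = 1, omega = 0), "omega")
  expect_error(sample_nakagami_envelope(0, nak = 1), "count")
})

test_that("nak = 1 draws are Rayleigh: intensity is exponential with mean omega", {
  a <- sample_nakagami_envelope(2e5, nak = 1, omega = 2, seed = 11)
  expect_equal(mean(a^2), 2, tolerance = 0.02)
  # exponential: var(A^2) = mean(A^2)^2
  expect_equal(var(a^2), mean(a^2)^2, tolerance = 0.05)
})

test_that("method-of-moments estimate recovers the sampling shape parameter", {
  a <- sample_nakagami_envelope(1e5, nak = 0.75, omega = 1, seed = 1)
  expect_lt(abs(nakagami_mom(a) - 0.75), 0.02)
  # second moment converges to omega
  expect_equal(mean(a^2), 1, tolerance = 0.02)
})

test_that("shape estimate is exactly scale invariant and draws are reproducible", {
  a <- sample_nakagami_envelope(5e3, nak = 0.6, omega = 3, seed = 7)
  b <- sample_nakagami_envelope(5e3, nak = 0.6, omega = 3, seed = 7)
  expect_identical(a, b)
  for (c in c(1e-3, 0.5, 10, 1e4)) {
    expect_equal(nakagami_mom(c * a), nakagami_mom(a), tolerance = 1e-12)
  }
})

test_that("empirical shape-parameter error shrinks roughly as 1/sqrt(n)", {
  err <- vapply(c(1e3, 1e5), function(n) {
    reps <- vapply(1:20, function(s) {
      nakagami_mom(sample_nakagami_envelope(n, 0.8, 1, seed = 100 + s))
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  # 100x the samples: SE should fall by ~10; allow a loose factor
  expect_lt(err[2], err[1] / 4)
})

test_that("uniform scene's recovered envelope is Rayleigh within tolerance", {
  sp <- scene_spec(grid_shape = c(1560L, 510L), lesion_semi_axes_mm = NULL,
                   seed = 1)
  env <- detect_envelope(make_speckle_rf(sp)$frame)
  expect_gte(length(env$values), 1e5)
  nak <- nakagami_mom(as.vector(env$values))
  expect_gt(nak, 0.95)
  expect_lt(nak, 1.05)
})

test_that("regional shape parameters are ordered as specified", {
  sp <- scene_spec(grid_shape = c(1040L, 260L),
                   lesion_semi_axes_mm = c(3, 2.5), rim_width_mm = 3,
                   interior_nak = 0.6, interior_omega = 1,
                   rim_nak = 1.4, rim_omega = 1, seed = 2)
  env <- detect_envelope(make_speckle_rf(sp)$frame)
  reg <- scene_region_ids(sp, dim(env$values), env$pixel_mm, env$pixel_mm)
  nak_int <- nakagami_mom(env$values[reg == 1L])
  nak_bg <- nakagami_mom(env$values[reg == 0L])
  nak_rim <- nakagami_mom(env$values[reg == 2L])
  expect_lt(nak_int, nak_bg)
  expect_lt(nak_bg, nak_rim)
})

test_that("degenerate scenes are rejected", {
  expect_error(make_speckle_rf(scene_spec(grid_shape = c(100L, 1L),
                                          lesion_semi_axes_mm = NULL)),
               "2 scan lines")
  # ellipse + rim must fit inside the grid
  expect_error(scene_spec(grid_shape = c(200L, 60L),
                          lesion_semi_axes_mm = c(3, 3)),
               "fit")
})

test_that("reference phantom: constant gain gives a flat correction curve", {
  ph <- make_reference_phantom(grid_shape = c(800L, 120L), depth_gain = 1,
                               seed = 3)
  curves <- phantom_correction_curves(ph, window_mm = 1, overlap = 0.5,
                                      params = "NAK")
  expect_equal(unname(curves$NAK$factor),
               rep(1, length(curves$NAK$factor)), tolerance = 0.1)
})

test_that("linear depth gain doubles the envelope mean bottom vs top", {
  ph <- make_reference_phantom(grid_shape = c(800L, 120L),
                               depth_gain = function(z) 1 + z / (800 * 0.01925),
                               seed = 4)
  env <- detect_envelope(ph)$values
  nr <- nrow(env)
  top <- mean(env[seq_len(nr %/% 8), ])
  bottom <- mean(env[(nr - nr %/% 8):nr, ])
  expect_equal(bottom / top, 2, tolerance = 0.1)
})

test_that("depth gain cancels in the shape estimate (scale invariance by depth)", {
  ph <- make_reference_phantom(grid_shape = c(800L, 120L), nak = 1,
                               depth_gain = function(z) 1 + z / (800 * 0.01925),
                               seed = 5)
  env <- detect_envelope(ph)$values
  bands <- cut(seq_len(nrow(env)), 4)
  for (b in levels(bands)) {
    nak <- nakagami_mom(as.vector(env[bands == b, ]))
    expect_gt(nak, 0.9)
    expect_lt(nak, 1.1)
  }
})

test_that("make_reference_phantom rejects non-positive gain", {
  expect_error(make_reference_phantom(grid_shape = c(100L, 10L),
                                      depth_gain = 0), "positive")
  expect_error(make_reference_phantom(grid_shape = c(100L, 10L),
                                      depth_gain = function(z) 1 - z),
               "positive")
})

test_that("cohorts have the configured structure and are deterministic", {
  spec <- tiny_cohort_spec(n_benign = 3L, n_malignant = 2L, seed = 42L)
  ch1 <- make_cohort(spec, materialize = TRUE)
  ch2 <- make_cohort(spec, materialize = TRUE)
  expect_identical(ch1, ch2)
  expect_equal(nrow(ch1$labels), 5L)
  expect_equal(sum(ch1$labels$label == "benign"), 3L)
  expect_equal(sum(vapply(ch1$lesions, function(l) length(l$frames),
                          integer(1))), 10L)  # 2 planes per lesion
  # contour traces the jittered truth ellipse and is closed
  cont <- ch1$lesions[[1]]$contour
  expect_equal(cont[1L, ], cont[nrow(cont), ])
  expect_equal(nrow(cont), 65L)
  # lazy and materialized frames agree
  ch3 <- make_cohort(spec, materialize = FALSE)
  expect_null(ch3$lesions[[1]]$frames)
  expect_equal(lesion_frames(ch3, 1L), ch1$lesions[[1]]$frames)
})

test_that("cohort counts validate", {
  expect_error(cohort_spec(n_benign = 0L), ">= 1")
  expect_error(cohort_spec(planes_per_lesion = 3L), "fixed at 2")
})
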