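test_that("Nakagami method of moments matches hand evaluation", {
  expect_equal(nakagami_mom(c(1, 1, 1, 3)), 0.75)
  for (c in c(0.01, 2, 500)) {
    expect_equal(nakagami_mom(c * c(1, 1, 1, 3)), 0.75, tolerance = 1e-12)
  }
  expect_true(is.na(nakagami_mom(c(2, 2, 2))))  # constant block
  expect_true(is.na(nakagami_mom(3)))
  a <- sample_nakagami_envelope(1e5, 1, 1, seed = 2)
  expect_lt(abs(nakagami_mom(a) - 1), 0.03)
})

test_that("weighted entropy matches hand evaluation and is non-negative", {
  expect_equal(weighted_entropy(c(5, 5, 5, 5)), 0)
  expect_equal(weighted_entropy(c(1, 1, 3, 3), n_bins = 2L), 0.5)
  set.seed(3)
  for (rep in 1:20) {
    a <- runif(50, 0, 10)
    expect_gte(weighted_entropy(a, 40L), 0)
  }
  expect_true(is.na(weighted_entropy(c(0, 0, 0))))
})

test_that("GLCM of a constant block is a single diagonal entry", {
  g <- compute_glcm(matrix(50, 8, 8), "vertical", 4L)
  expect_equal(sum(g), 1)
  q <- quantize_db(matrix(50, 1, 1))[1, 1]
  expect_equal(g[q, q], 1)
  f <- glcm_features(g)
  expect_equal(unname(f["CON"]), 0)
  expect_equal(unname(f["ENE"]), 1)
  expect_equal(unname(f["HOM"]), 1)
  expect_equal(unname(f["VAR"]), 0)
  expect_true(is.na(f["COR"]))
})

test_that("checkerboard GLCM matches hand evaluation", {
  q <- checkerboard(6L)
  for (dirn in c("horizontal", "vertical")) {
    g <- compute_glcm(q, dirn, 1L, levels = 2L, quantized = TRUE)
    expect_equal(g, matrix(c(0, 0.5, 0.5, 0), 2, 2))
    f <- glcm_features(g)
    expect_equal(unname(f["CON"]), 1)
    expect_equal(unname(f["ENE"]), 0.5)
    expect_equal(unname(f["HOM"]), 0.5)
    expect_equal(unname(f["VAR"]), 0.25)
    expect_equal(unname(f["COR"]), -1)
  }
})

test_that("GLCM features agree with the brute-force pair oracle", {
  set.seed(7)
  for (rep in 1:50) {
    q <- matrix(sample.int(20L, 100, replace = TRUE), 10, 10)
    d <- sample(1:4, 1)
    dirn <- sample(c("vertical", "horizontal"), 1)
    g <- compute_glcm(q, dirn, d, levels = 20L, quantized = TRUE)
    expect_equal(g, brute_glcm(q, dirn, d, 20L), tolerance = 1e-15)
    f1 <- glcm_features(g)
    f2 <- brute_glcm_features(g)
    expect_equal(f1[c("CON", "ENE", "HOM", "VAR")],
                 f2[c("CON", "ENE", "HOM", "VAR")], tolerance = 1e-14)
    expect_identical(is.na(f1["COR"]), is.na(f2["COR"]))
    if (!is.na(f1["COR"])) {
      expect_lte(abs(f1[["COR"]] - f2[["COR"]]), 1e-12)
    }
    expect_equal(sum(g), 1)
    expect_true(f1["ENE"] > 0 && f1["ENE"] <= 1)
    expect_true(f1["HOM"] > 0 && f1["HOM"] <= 1)
    if (!is.na(f1["COR"])) expect_true(abs(f1["COR"]) <= 1 + 1e-12)
  }
})

test_that("blocks too small for the displacement are invalid", {
  expect_null(compute_glcm(matrix(50, 3, 8), "vertical", 4L))
  expect_null(compute_glcm(matrix(50, 8, 3), "horizontal", 4L))
})

test_that("parametric maps recover homogeneous and two-region truth", {
  sp <- scene_spec(grid_shape = c(1040L, 200L), lesion_semi_axes_mm = NULL,
                   background_nak = 1, seed = 21)
  env <- detect_envelope(make_speckle_rf(sp)$frame)
  w <- place_windows(dim(env$values), env$pixel_mm, 1, overlap = 0)
  map <- build_parametric_map(env, w, "NAK")
  vals <- map$values[map$valid]
  expect_lt(abs(mean(vals) - 1), 3 * sd(vals) / sqrt(length(vals)) + 0.02)

  sp2 <- scene_spec(grid_shape = c(1040L, 200L),
                    lesion_semi_axes_mm = c(2.5, 2), rim_width_mm = 0.5,
                    interior_nak = 0.5, interior_omega = 1,
                    rim_nak = 1, rim_omega = 1, seed = 22)
  env2 <- detect_envelope(make_speckle_rf(sp2)$frame)
  w2 <- place_windows(dim(env2$values), env2$pixel_mm, 1, overlap = 0)
  map2 <- build_parametric_map(env2, w2, "NAK")
  reg <- scene_region_ids(sp2, dim(env2$values), env2$pixel_mm,
                          env2$pixel_mm)
  ctr <- cbind(rep(w2$row_start + w2$window_px %/% 2L,
                   times = length(w2$col_start)),
               rep(w2$col_start + w2$window_px %/% 2L,
                   each = length(w2$row_start)))
  win_reg <- matrix(reg[ctr], nrow(map2$values))
  inside <- map2$values[win_reg == 1L & map2$valid]
  outside <- map2$values[win_reg == 0L & map2$valid]
  expect_lt(mean(inside), mean(outside) - 0.2)
})

test_that("unknown estimator names are rejected", {
  env <- envelope_image(matrix(runif(400), 20), 0.075)
  w <- place_windows(c(20L, 20L), 0.075, 1, 0)
  expect_error(build_parametric_map(env, w, "FOO"), "unknown parameter")
})

test_that("the multi-map engine matches the single-parameter builder", {
  sp <- tiny_scene(seed = 31)
  env <- detect_envelope(make_speckle_rf(sp)$frame)
  bm <- log_compress(env)
  w <- place_windows(dim(env$values), env$pixel_mm, 1, overlap = 0)
  maps <- build_parametric_maps(env, bm, w)
  for (pp in qus_parameters()) {
    img <- if (pp %in% c("NAK", "ENT")) env else bm
    ref <- build_parametric_map(img, w, pp)
    expect_equal(maps[[pp]]$values, ref$values, tolerance = 1e-10,
                 label = pp)
    expect_identical(maps[[pp]]$valid, ref$valid)
  }
})

test_that("roi_average pools valid windows across planes", {
  mk <- function(vals) {
    parametric_map("NAK", vals, !is.na(vals),
                   (seq_len(nrow(vals)) - 0.5) * 0.075, 0.075)
  }
  mA <- mk(matrix(c(1, 3, 99, 99), 2, 2))
  mB <- mk(matrix(c(5, 7, 99, 99), 2, 2))
  asg <- data.frame(ai = c(1L, 2L), li = c(1L, 1L))
  expect_equal(roi_average(list(mA, mB), list(asg, asg)), 4)
  # identical constant maps return the constant
  mC <- mk(matrix(2, 2, 2))
  expect_equal(roi_average(list(mC, mC), list(asg, asg)), 2)
  # empty assignment: missing
  empty <- data.frame(ai = integer(0), li = integer(0))
  expect_true(is.na(roi_average(list(mA), list(empty))))
})

test_that("extract_features returns the 24-column table deterministically", {
  spec <- tiny_cohort_spec(2L, 2L, seed = 8L)
  cohort <- make_cohort(spec, materialize = TRUE)
  tab <- tiny_extract(cohort)
  expect_equal(nrow(tab), 4L)
  expect_equal(names(tab),
               c("lesion_id", "label",
                 paste0(qus_parameters(), "_int"),
                 paste0(qus_parameters(), "_ext")))
  expect_false(anyNA(tab))
  # deterministic given inputs
  expect_equal(tiny_extract(cohort), tab)
  # permuting lesion order permutes rows only
  cohort_p <- cohort
  perm <- c(3L, 1L, 4L, 2L)
  cohort_p$lesions <- cohort$lesions[perm]
  tab_p <- tiny_extract(cohort_p)
  expect_equal(tab_p[order(tab_p$lesion_id), ],
               tab[order(tab$lesion_id), ], ignore_attr = TRUE)
})

test_that("parametric map ranges respect the documented invariants", {
  spec <- tiny_cohort_spec(1L, 1L, seed = 12L)
  cohort <- make_cohort(spec, materialize = TRUE)
  env <- detect_envelope(cohort$lesions[[1]]$frames[[1]])
  bm <- log_compress(env)
  w <- place_windows(dim(env$values), env$pixel_mm, 1, overlap = 0)
  maps <- build_parametric_maps(env, bm, w)
  expect_true(all(maps$NAK$values[maps$NAK$valid] > 0))
  for (pp in c("ENEV", "ENEH", "HOMV", "HOMH")) {
    v <- maps[[pp]]$values[maps[[pp]]$valid]
    expect_true(all(v > 0 & v <= 1), label = pp)
  }
  for (pp in c("CONV", "CONH", "VARV", "VARH")) {
    expect_true(all(maps[[pp]]$values[maps[[pp]]$valid] >= 0), label = pp)
  }
  for (pp in c("CORV", "CORH")) {
    v <- maps[[pp]]$values[maps[[pp]]$valid]
    expect_true(all(abs(v) <= 1 + 1e-12), label = pp)
  }
})
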