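test_that("well-separated clusters get extreme LOOCV scores", {
  tab <- toy_feature_table(10L, 10L, m_info = 1L, m_noise = 0L,
                           delta = 50, seed = 2)
  sc <- knn_loocv_scores(tab[, "F1", drop = FALSE], tab$label, k = 4L)
  expect_equal(sc[tab$label == "malignant"], rep(1, 10))
  expect_equal(sc[tab$label == "benign"], rep(0, 10))
})

test_that("LOOCV needs k + 1 lesions and both classes", {
  tab <- toy_feature_table(2L, 2L, seed = 1)
  expect_error(knn_loocv_scores(tab[, 3:4], tab$label, k = 4L), "k \\+ 1")
  one_class <- toy_feature_table(6L, 6L, seed = 1)
  expect_error(knn_loocv_scores(one_class[, 3:4],
                                rep("benign", 12)), "both classes")
})

test_that("C++ scorer agrees with the pure-R reference route", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(12:30, 1)
    m <- sample(1:5, 1)
    x <- matrix(rnorm(n * m), n)
    y <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("benign", "malignant")
    expect_equal(knn_loocv_scores(x, y, k = 4L),
                 qusrim:::knn_loocv_scores_ref(x, y, k = 4L),
                 tolerance = 1e-12)
  }
})

test_that("fold standardization does not leak the held-out case", {
  # an uninformative constant-plus-noise feature must stay at chance
  set.seed(4)
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(10 + rnorm(60, sd = 1e-3), 60, 1)
    y <- rep(c("benign", "malignant"), 30)
    roc_auc(knn_loocv_scores(x, y, k = 4L), y)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("zero-variance features are dropped with a warning", {
  x <- cbind(const = rep(1, 20), good = c(rnorm(10), rnorm(10, 6)))
  y <- rep(c("benign", "malignant"), each = 10)
  expect_warning(sc <- knn_loocv_scores(x, y, k = 4L), "zero training-fold")
  expect_equal(roc_auc(sc, y)$auc, 1)
})

test_that("ROC AUC matches the printed 4-point example and edge cases", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c("benign", "benign", "malignant", "malignant")
  expect_equal(roc_auc(scores, labels)$auc, 0.75)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(0, 0, 1, 1), labels)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 4), labels)$auc, 0.5)
  expect_error(roc_auc(1:4, rep("benign", 4)), "both classes")
})

test_that("ROC AUC equals the Mann-Whitney pair-count oracle", {
  set.seed(10)
  for (rep in 1:200) {
    n <- sample(6:40, 1)
    y <- c("benign", "malignant",
           sample(c("benign", "malignant"), n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(s, y)$auc, auc_pairs_oracle(s, y),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve is a valid staircase from (0,0) to (1,1)", {
  set.seed(11)
  y <- sample(c("benign", "malignant"), 30, replace = TRUE)
  y[1:2] <- c("benign", "malignant")
  r <- roc_auc(runif(30), y)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("operating point maximizes Youden's J with sensitivity tie-break", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c("benign", "benign", "malignant", "malignant")
  op <- operating_point(scores, labels)
  # two thresholds tie at J = 0.5; tie-break prefers the sensitive one
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 0.5)
  expect_equal(op$accuracy, 0.75)
  expect_false(op$degenerate)

  perfect <- operating_point(c(0, 0, 1, 1), labels)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  flat <- operating_point(rep(0.3, 4), labels)
  expect_true(flat$degenerate)
  expect_equal(flat$sensitivity, 1)
  expect_equal(flat$specificity, 0)
})

test_that("rank-sum test matches exact enumeration and classifies p-values", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)  # 2 of C(6,3)=20 equally likely extremes
  expect_equal(rs$significance_class, "non-significant")

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$significance_class, "non-significant")

  expect_equal(significance_class(0.0005), "***")
  expect_equal(significance_class(0.005), "**")
  expect_equal(significance_class(0.04), "*")
  expect_equal(significance_class(0.2), "non-significant")
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("exhaustive search enumerates 2^m - 1 subsets and finds the brute-force best", {
  tab <- synthetic_qus_table(10L, 10L, effect_cols = c("NAK_int"),
                             delta = 3, seed = 3)
  feats <- c("NAK_int", "ENT_int", "CONV_int")
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(feats, k, simplify = FALSE)
  }), recursive = FALSE)
  brute <- vapply(combos, function(fs) {
    roc_auc(knn_loocv_scores(tab[, fs, drop = FALSE], tab$label, 4L),
            tab$label)$auc
  }, numeric(1))

  # full 12-feature internal group
  sr <- exhaustive_search(tab, "internal", metrics = "auc")
  expect_equal(sr$n_subsets, 4095L)
  expect_equal(nrow(sr$reports), 4095L)

  # 3-feature toy group: 7 reports, matched subset-by-subset to the
  # single-call route
  sr3 <- exhaustive_search(tab, columns = feats, metrics = "auc")
  expect_equal(sr3$n_subsets, 7L)
  nm <- vapply(combos, paste, "", collapse = "+")
  got <- sr3$reports$auc[match(nm, sr3$reports$features)]
  expect_equal(unname(got), brute, tolerance = 1e-10)
  # the best AUC dominates every single-feature AUC
  singles <- sr3$reports$auc[sr3$reports$n_features == 1L]
  expect_gte(sr3$best$auc, max(singles))
})

test_that("subset counts are exactly 2^m - 1 and 1-feature search equals the SPC", {
  tab <- synthetic_qus_table(8L, 8L, effect_cols = "ENT_int", delta = 2,
                             seed = 5)
  cols <- paste0(qus_parameters(), "_int")
  for (m in c(1L, 2L, 5L, 8L)) {
    sr <- exhaustive_search(tab, columns = cols[seq_len(m)],
                            metrics = "auc")
    expect_equal(sr$n_subsets, 2L^m - 1L)
  }
  spc <- exhaustive_search(tab, columns = "ENT_int")
  expect_equal(nrow(spc$reports), 1L)
  expect_equal(spc$best$auc,
               roc_auc(knn_loocv_scores(tab[, "ENT_int", drop = FALSE],
                                        tab$label, 4L), tab$label)$auc,
               tolerance = 1e-12)
})

test_that("full-metrics reports carry consistent operating points and p-values", {
  tab <- synthetic_qus_table(12L, 12L, effect_cols = c("NAK_int", "ENT_int"),
                             delta = 2.5, seed = 6)
  tab3 <- tab[, c("lesion_id", "label", paste0(qus_parameters(), "_int"))]
  sr <- exhaustive_search(tab, "internal", metrics = "full")
  rp <- sr$reports
  expect_true(all(rp$auc >= 0 & rp$auc <= 1))
  expect_true(all(rp$sensitivity >= 0 & rp$sensitivity <= 1))
  expect_true(all(rp$specificity >= 0 & rp$specificity <= 1))
  expect_true(all(rp$accuracy >= 0 & rp$accuracy <= 1))
  expect_true(all(rp$p_value >= 0 & rp$p_value <= 1))
  cls <- vapply(rp$p_value, significance_class, "")
  expect_identical(rp$significance, cls)
  # sorted by AUC descending, lexicographic tie-break
  expect_true(all(diff(rp$auc) <= 1e-15))
})

test_that("compare_groups pairs matched subsets", {
  tab <- synthetic_qus_table(10L, 10L, seed = 7)
  # identical features for both ROIs => all deltas zero
  for (p in qus_parameters()) tab[[paste0(p, "_ext")]] <- tab[[paste0(p, "_int")]]
  si <- exhaustive_search(tab, "internal", metrics = "auc")
  se <- exhaustive_search(tab, "external", metrics = "auc")
  cmp <- compare_groups(si, se)
  expect_equal(cmp$n_subsets, 4095L)
  expect_equal(cmp$table$delta_auc, rep(0, 4095))
  expect_equal(cmp$n_internal_wins, 0L)
})
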