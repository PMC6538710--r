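as_label01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("benign", "malignant"))
    if (length(bad) > 0L) stopf("unknown label(s): %s",
                                paste(bad, collapse = ", "))
    return(as.integer(labels == "malignant"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    return(as.integer(labels))
  }
  stopf("labels must be benign/malignant, logical, or 0/1")
}

# Fold-scaled squared-difference cube M[i, j, f] =
# (x[i,f] - x[j,f])^2 / var_f^(-i), with var the training-fold (excluding
# i) sample variance. Zero-variance folds drop the feature (slice set to 0)
# with a warning.
fold_distance_cube <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  M <- array(0, c(n, n, m))
  warned <- FALSE
  for (f in seq_len(m)) {
    v <- x[, f]
    s1 <- sum(v); s2 <- sum(v * v)
    mu_i <- (s1 - v) / (n - 1)
    var_i <- (s2 - v * v - (n - 1) * mu_i^2) / (n - 2)
    var_i[var_i < 0] <- 0  # guard against cancellation
    d2 <- outer(v, v, `-`)^2
    scale_i <- ifelse(var_i > 0, 1 / var_i, 0)
    if (any(var_i == 0)) warned <- TRUE
    M[, , f] <- d2 * scale_i  # rows are the held-out index i
  }
  if (warned) {
    warnf("feature with zero training-fold variance dropped for some folds")
  }
  M
}

#' Leave-one-out k-NN malignancy scores
#'
#' For each held-out lesion, features are standardized by the training
#' fold's mean and standard deviation, the `k` nearest training lesions by
#' Euclidean distance in the standardized space are found (all neighbours
#' tied with the k-th distance are included), and the score is the fraction
#' of malignant lesions among them. Standardization uses training-fold
#' statistics only, so no information from the held-out case leaks into
#' the distance metric; a feature with zero training-fold variance is
#' dropped for that fold with a warning.
#'
#' @param x matrix or data frame of feature columns (lesions in rows).
#' @param labels per-lesion labels (`"benign"`/`"malignant"`, logical, or
#'   0/1 with 1 = malignant).
#' @param k number of neighbours (default 4).
#' @return Numeric vector of malignancy scores in `[0, 1]`.
#' @export
knn_loocv_scores <- function(x, labels, k = 4L) {
  x <- as.matrix(x)
  y <- as_label01(labels)
  n <- nrow(x)
  if (n < k + 1L) stopf("need at least k + 1 = %d lesions for LOOCV", k + 1L)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  if (length(y) != n) stopf("labels length must match rows of x")
  M <- fold_distance_cube(x)
  .knn_loocv_cpp(as.numeric(M), n, ncol(x), y, as.integer(k))
}

# Pure-R reference route for the LOOCV scorer (used as an independent
# oracle in tests; O(n^2 m) per call).
knn_loocv_scores_ref <- function(x, labels, k = 4L) {
  x <- as.matrix(x)
  y <- as_label01(labels)
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    sds <- apply(x[tr, , drop = FALSE], 2L, sd)
    use <- sds > 0
    d <- vapply(tr, function(j) {
      sum(((x[i, use] - x[j, use]) / sds[use])^2)
    }, numeric(1))
    dk <- sort(d, partial = k)[k]
    nb <- tr[d <= dk + 1e-8 * max(dk, 1e-300)]
    mean(y[nb])
  }, numeric(1))
}

#' ROC curve and AUC
#'
#' AUC in the Mann-Whitney formulation: the probability that a malignant
#' score exceeds a benign one, ties counted one half. The curve enumerates
#' all score thresholds (classify malignant when score >= threshold).
#'
#' @param scores per-lesion malignancy scores.
#' @param labels per-lesion labels.
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label01(labels)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Operating point on the ROC curve
#'
#' Chooses the threshold maximizing Youden's J (sensitivity + specificity
#' - 1); J ties are broken toward higher sensitivity. Accuracy is reported
#' at the selected threshold. When all scores are equal the point is
#' degenerate (sensitivity 1, specificity 0) and flagged.
#'
#' @inheritParams roc_auc
#' @return List `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `degenerate`.
#' @export
operating_point <- function(scores, labels) {
  y <- as_label01(labels)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0L] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(sens[best])]
  t0 <- thr[best]
  acc <- mean((scores >= t0) == (y == 1L))
  list(threshold = t0, sensitivity = sens[best], specificity = spec[best],
       accuracy = acc, degenerate = length(thr) == 1L)
}

#' Two-sided Wilcoxon rank-sum test with significance classes
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; tie-corrected normal approximation (with continuity
#' correction) otherwise. The p-value is mapped to the reporting classes
#' `non-significant` (p >= 0.05), `*` (p < 0.05), `**` (p < 0.01),
#' `***` (p < 0.001).
#'
#' @param benign,malignant numeric value vectors for the two groups.
#' @return List `p_value`, `significance_class`.
#' @export
rank_sum_test <- function(benign, malignant) {
  if (length(benign) < 1L || length(malignant) < 1L) {
    stopf("both groups must be non-empty")
  }
  total <- length(benign) + length(malignant)
  ties <- anyDuplicated(c(benign, malignant)) > 0L
  p <- suppressWarnings(
    wilcox.test(malignant, benign, alternative = "two.sided",
                exact = total <= 20L && !ties, correct = TRUE)$p.value)
  list(p_value = p, significance_class = significance_class(p))
}

#' @rdname rank_sum_test
#' @param p a p-value.
#' @export
significance_class <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "non-significant"
}

group_columns <- function(table, group) {
  switch(group,
         internal = paste0(QUS_PARAMS, "_int"),
         external = paste0(QUS_PARAMS, "_ext"),
         combined = c(paste0(QUS_PARAMS, "_int"),
                      paste0(QUS_PARAMS, "_ext")))
}

#' Exhaustive feature-subset k-NN search
#'
#' Evaluates every non-empty subset of the group's feature columns with the
#' leave-one-out k-NN classifier and ROC analysis: `2^m - 1` classifiers
#' for `m` features (4095 for one 12-parameter ROI group). Reports are
#' sorted by AUC descending with a deterministic lexicographic tie-break
#' on the subset name.
#'
#' @param table feature table from [extract_features()] (columns
#'   `lesion_id`, `label`, then feature columns).
#' @param group `"internal"`, `"external"` or `"combined"` (all 24).
#' @param columns optional explicit feature columns, overriding `group`
#'   (useful for toy groups and sub-searches).
#' @param k number of neighbours (default 4).
#' @param metrics `"full"` adds the Youden operating point and rank-sum
#'   p-value per subset; `"auc"` computes AUC only (faster).
#' @return A `search_result`: `reports` (data frame, one row per subset),
#'   `best` (highest-AUC row), `n_subsets`, `group`, `features`.
#' @export
exhaustive_search <- function(table, group = c("internal", "external",
                                               "combined"),
                              columns = NULL, k = 4L,
                              metrics = c("full", "auc")) {
  group <- match.arg(group)
  metrics <- match.arg(metrics)
  cols <- if (is.null(columns)) group_columns(table, group) else columns
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0L) {
    stopf("feature table lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(table[, cols, drop = FALSE])
  y <- as_label01(table$label)
  n <- nrow(x); m <- ncol(x)
  if (m < 1L) stopf("empty feature group")
  if (m > 20L) {
    stopf(paste("exhaustive enumeration of %d features (2^%d - 1 subsets)",
                "exceeds the supported range; restrict `columns`"), m, m)
  }
  if (!is.null(columns)) group <- "custom"
  if (n < k + 1L) stopf("need at least k + 1 lesions")
  M <- fold_distance_cube(x)
  res <- .knn_exhaustive_cpp(as.numeric(M), n, m, y, as.integer(k),
                             metrics == "full")
  nsub <- length(res$auc)
  subset_name <- vapply(res$subset, function(mask) {
    f <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    paste(cols[f], collapse = "+")
  }, character(1))
  size <- vapply(res$subset, function(mask) {
    sum(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
  }, integer(1))

  reports <- data.frame(subset_id = res$subset, features = subset_name,
                        n_features = size, auc = res$auc,
                        stringsAsFactors = FALSE)
  if (metrics == "full") {
    n_rep <- nrow(reports)
    sens <- spec <- acc <- pval <- numeric(n_rep)
    cls <- character(n_rep)
    ben <- y == 0L
    for (q in seq_len(n_rep)) {
      sc <- res$scores[, q]
      op <- operating_point(sc, y)
      sens[q] <- op$sensitivity; spec[q] <- op$specificity
      acc[q] <- op$accuracy
      rs <- rank_sum_test(sc[ben], sc[!ben])
      pval[q] <- rs$p_value
      cls[q] <- rs$significance_class
    }
    reports$sensitivity <- sens
    reports$specificity <- spec
    reports$accuracy <- acc
    reports$p_value <- pval
    reports$significance <- cls
  }
  ord <- order(-reports$auc, reports$features)
  reports <- reports[ord, , drop = FALSE]
  rownames(reports) <- NULL
  structure(list(reports = reports, best = reports[1L, , drop = FALSE],
                 n_subsets = nsub, group = group, features = cols,
                 k = k, n_lesions = n),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s: %d subsets of %d features, best AUC %.3f (%s)\n",
              x$group, x$n_subsets, length(x$features), x$best$auc,
              x$best$features))
  invisible(x)
}

#' Compare matched external and internal classifiers
#'
#' Pairs every feature subset of the external search with the same
#' parameter subset of the internal search and reports
#' `delta_auc = auc_external - auc_internal`, plus summary counts (how
#' often the internal classifier wins) and a histogram of the differences.
#'
#' @param internal,external `search_result`s over the internal and
#'   external 12-parameter groups.
#' @param breaks histogram breaks for the delta-AUC summary.
#' @return List `table` (subset_id, parameters, auc_internal,
#'   auc_external, delta_auc), `n_internal_wins`, `n_subsets`, `histogram`.
#' @export
compare_groups <- function(internal, external,
                           breaks = seq(-1, 1, by = 0.02)) {
  stopifnot(inherits(internal, "search_result"),
            inherits(external, "search_result"))
  if (internal$n_subsets != external$n_subsets) {
    stopf("searches enumerate different numbers of subsets")
  }
  ti <- internal$reports[order(internal$reports$subset_id), ]
  te <- external$reports[order(external$reports$subset_id), ]
  if (!identical(ti$subset_id, te$subset_id)) {
    stopf("subset enumerations do not match")
  }
  params <- sub("_int", "", ti$features, fixed = TRUE)
  delta <- te$auc - ti$auc
  hist_counts <- table(cut(delta, breaks = breaks, include.lowest = TRUE))
  list(table = data.frame(subset_id = ti$subset_id, parameters = params,
                          auc_internal = ti$auc, auc_external = te$auc,
                          delta_auc = delta, stringsAsFactors = FALSE),
       n_internal_wins = sum(delta < 0),
       n_subsets = length(delta),
       histogram = hist_counts)
}
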