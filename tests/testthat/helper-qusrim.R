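# Fixture builders and independent oracles used across the suite.

# Small, fast scene/cohort: ~10 x 10 mm grid, 1.6 x 1.4 mm lesion, 2 mm rim.
tiny_scene <- function(..., seed = NULL) {
  scene_spec(grid_shape = c(520L, 132L),
             lesion_semi_axes_mm = c(1.6, 1.4), rim_width_mm = 2,
             ..., seed = seed)
}

tiny_cohort_spec <- function(n_benign = 2L, n_malignant = 2L, seed = 1L,
                             effect = "rim") {
  malignant <- switch(effect,
    rim = tiny_scene(rim_nak = 0.7, rim_omega = 1.25),
    interior = tiny_scene(interior_nak = 0.55, interior_omega = 0.6),
    none = tiny_scene())
  cohort_spec(n_benign = n_benign, n_malignant = n_malignant,
              benign_scene = tiny_scene(), malignant_scene = malignant,
              seed = seed)
}

tiny_extract <- function(cohort, ...) {
  extract_features(cohort, overlap = 0, rim_width_mm = 2, ...)
}

# Labeled synthetic feature table: m_info informative features (class shift
# `delta`), m_noise pure-noise features.
toy_feature_table <- function(n_benign, n_malignant, m_info = 2L,
                              m_noise = 2L, delta = 2, seed = 1L,
                              prefix = "F") {
  set.seed(seed)
  n <- n_benign + n_malignant
  lab <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  x <- matrix(rnorm(n * (m_info + m_noise)), n)
  if (m_info > 0L) {
    x[lab == "malignant", seq_len(m_info)] <-
      x[lab == "malignant", seq_len(m_info)] + delta
  }
  colnames(x) <- paste0(prefix, seq_len(m_info + m_noise))
  cbind(data.frame(lesion_id = sprintf("T%03d", seq_len(n)), label = lab,
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}

# Feature table shaped like extract_features() output (24 columns), with
# the class effect placed in chosen columns.
synthetic_qus_table <- function(n_benign = 59L, n_malignant = 57L,
                                effect_cols = character(0), delta = 1.5,
                                seed = 1L) {
  set.seed(seed)
  n <- n_benign + n_malignant
  lab <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  cols <- c(paste0(qus_parameters(), "_int"),
            paste0(qus_parameters(), "_ext"))
  x <- matrix(rnorm(n * 24L), n, dimnames = list(NULL, cols))
  for (cc in effect_cols) {
    x[lab == "malignant", cc] <- x[lab == "malignant", cc] + delta
  }
  cbind(data.frame(lesion_id = sprintf("S%03d", seq_len(n)), label = lab,
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}

# Independent GLCM oracle: explicit enumeration of ordered pixel pairs.
brute_glcm <- function(q, direction, d, levels) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (direction == "vertical" && r + d <= nr) {
        counts[q[r, c], q[r + d, c]] <- counts[q[r, c], q[r + d, c]] + 1
      }
      if (direction == "horizontal" && c + d <= nc) {
        counts[q[r, c], q[r, c + d]] <- counts[q[r, c], q[r, c + d]] + 1
      }
    }
  }
  counts / sum(counts)
}

# Independent Haralick oracle: direct double-sum evaluation.
brute_glcm_features <- function(g) {
  L <- nrow(g)
  mui <- muj <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    mui <- mui + i * g[i, j]; muj <- muj + j * g[i, j]
  }
  vi <- vj <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    vi <- vi + (i - mui)^2 * g[i, j]; vj <- vj + (j - muj)^2 * g[i, j]
  }
  con <- cor_n <- ene <- hom <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    con <- con + abs(i - j)^2 * g[i, j]
    cor_n <- cor_n + (i - mui) * (j - muj) * g[i, j]
    ene <- ene + g[i, j]^2
    hom <- hom + g[i, j] / (1 + abs(i - j)^2)
  }
  cor <- if (vi == 0 || vj == 0) NA_real_ else cor_n / sqrt(vi * vj)
  c(CON = con, COR = cor, ENE = ene, HOM = hom, VAR = vi)
}

# Independent AUC oracle: exhaustive concordant-pair counting.
auc_pairs_oracle <- function(scores, labels) {
  mal <- scores[labels == "malignant" | labels == 1]
  ben <- scores[labels == "benign" | labels == 0]
  conc <- 0
  for (m in mal) for (b in ben) {
    conc <- conc + if (m > b) 1 else if (m == b) 0.5 else 0
  }
  conc / (length(mal) * length(ben))
}

# 2-level checkerboard block quantized to levels {1, 2}.
checkerboard <- function(n = 6L) {
  outer(seq_len(n), seq_len(n), function(r, c) ((r + c) %% 2L) + 1L)
}
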