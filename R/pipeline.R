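#' Pipeline configuration
#'
#' Assembles and validates the configuration for the end-to-end study.
#' Defaults are the reference analysis settings: 5-mm rim, 1-mm windows at
#' 92% overlap, 20-100 dB dynamic range quantized into 20 gray levels,
#' 0.3-mm GLCM displacement, 40 entropy bins, k = 4 neighbours.
#'
#' @param rim_width_mm external rim width (> 0).
#' @param window_mm sliding-window size.
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param db_range B-mode dynamic range (low, high).
#' @param gray_levels GLCM gray levels.
#' @param displacement_mm GLCM displacement.
#' @param entropy_bins entropy histogram bins.
#' @param k k-NN neighbour count.
#' @param correction `"off"`, `"multiplicative"` or `"additive"` phantom
#'   correction of parametric maps (`"off"` unless a phantom is supplied).
#' @param seed master seed for synthesis.
#' @param cohort optional [cohort_spec()] to synthesize, or `NULL` when a
#'   cohort bundle is passed to [run_pipeline()] directly.
#' @param metrics passed to [exhaustive_search()] (`"full"` or `"auc"`).
#' @param cache_dir optional directory for content-addressed stage caching.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(rim_width_mm = 5, window_mm = 1,
                            overlap = 0.92, db_range = c(20, 100),
                            gray_levels = 20L, displacement_mm = 0.3,
                            entropy_bins = 40L, k = 4L,
                            correction = c("off", "multiplicative",
                                           "additive"),
                            seed = 1L, cohort = NULL,
                            metrics = c("full", "auc"),
                            cache_dir = NULL) {
  cfg <- list(rim_width_mm = rim_width_mm, window_mm = window_mm,
              overlap = overlap, db_range = db_range,
              gray_levels = as.integer(gray_levels),
              displacement_mm = displacement_mm,
              entropy_bins = as.integer(entropy_bins), k = as.integer(k),
              correction = match.arg(correction), seed = seed,
              cohort = cohort, metrics = match.arg(metrics),
              cache_dir = cache_dir)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Applies all range checks and rejects unknown keys; errors are collected
#' and reported together.
#'
#' @param config a `pipeline_config` (or plain named list with the same
#'   keys).
#' @return The validated config (invisibly classed `pipeline_config`).
#' @export
validate_config <- function(config) {
  known <- c("rim_width_mm", "window_mm", "overlap", "db_range",
             "gray_levels", "displacement_mm", "entropy_bins", "k",
             "correction", "seed", "cohort", "metrics", "cache_dir")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    errs <- c(errs, sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$rim_width_mm) && config$rim_width_mm > 0,
      "rim_width_mm must be > 0")
  chk(is.numeric(config$window_mm) && config$window_mm > 0,
      "window_mm must be > 0")
  chk(is.numeric(config$overlap) && config$overlap >= 0 &&
        config$overlap < 1, "overlap must be in [0, 1)")
  chk(length(config$db_range) == 2L &&
        config$db_range[1L] < config$db_range[2L],
      "db_range must be (low, high) with low < high")
  chk(is.numeric(config$gray_levels) && config$gray_levels >= 2,
      "gray_levels must be >= 2")
  chk(is.numeric(config$displacement_mm) && config$displacement_mm > 0,
      "displacement_mm must be > 0")
  chk(is.numeric(config$entropy_bins) && config$entropy_bins >= 2,
      "entropy_bins must be >= 2")
  chk(is.numeric(config$k) && config$k >= 1, "k must be >= 1")
  chk(config$correction %in% c("off", "multiplicative", "additive"),
      "correction must be off/multiplicative/additive")
  chk(is.null(config$cohort) || inherits(config$cohort, "cohort_spec"),
      "cohort must be NULL or a cohort_spec")
  if (length(errs) > 0L) {
    stopf("invalid configuration:\n- %s", paste(errs, collapse = "\n- "))
  }
  class(config) <- "pipeline_config"
  invisible(config)
}

stage_cached <- function(cache_dir, stage, key_obj, fun) {
  if (is.null(cache_dir)) return(fun())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- object_hash(list(stage = stage, key = key_obj))
  path <- file.path(cache_dir, paste0(stage, "-", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  out <- fun()
  saveRDS(out, path)
  out
}

#' Run the end-to-end study
#'
#' Synthesize (or accept) a cohort, extract the 24-feature table, run the
#' exhaustive k-NN subset search for the internal, external and combined
#' groups, and pair internal with external classifiers. With a
#' `cache_dir`, stage outputs are content-addressed by their inputs, so
#' unchanged stages are reused on reruns without changing results.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `qus_cohort`; if `NULL`, synthesized
#'   from `config$cohort` (required then).
#' @param phantom optional [rf_frame()] of a homogeneous reference phantom
#'   used to estimate correction curves when `config$correction != "off"`.
#' @param verbose print progress.
#' @return List `features`, `search` (internal/external/combined),
#'   `comparison`, `summary` (plain list, JSON-serializable).
#' @export
run_pipeline <- function(config, cohort = NULL, phantom = NULL,
                         verbose = FALSE) {
  config <- validate_config(config)
  if (is.null(cohort)) {
    if (is.null(config$cohort)) {
      stopf("no cohort: supply `cohort` or set config$cohort")
    }
    cohort <- stage_cached(config$cache_dir, "synth", config$cohort,
                           function() make_cohort(config$cohort))
  }

  correction <- NULL
  if (config$correction != "off") {
    if (is.null(phantom)) stopf("phantom frame required for correction")
    correction <- phantom_correction_curves(
      phantom, mode = config$correction, window_mm = config$window_mm,
      overlap = config$overlap, db_range = config$db_range,
      levels = config$gray_levels,
      displacement_mm = config$displacement_mm,
      entropy_bins = config$entropy_bins)
  }

  features <- stage_cached(
    config$cache_dir, "extract",
    list(cohort = cohort$spec, cfg = config[c("rim_width_mm", "window_mm",
                                              "overlap", "db_range",
                                              "gray_levels",
                                              "displacement_mm",
                                              "entropy_bins",
                                              "correction")]),
    function() extract_features(
      cohort, window_mm = config$window_mm, overlap = config$overlap,
      rim_width_mm = config$rim_width_mm, db_range = config$db_range,
      levels = config$gray_levels,
      displacement_mm = config$displacement_mm,
      entropy_bins = config$entropy_bins, correction = correction,
      verbose = verbose))

  search <- stage_cached(
    config$cache_dir, "classify",
    list(features = features, k = config$k, metrics = config$metrics),
    function() {
      res <- lapply(stats::setNames(nm = c("internal", "external")),
                    function(g) exhaustive_search(features, g,
                                                  k = config$k,
                                                  metrics = config$metrics))
      # Full enumeration of the 24-feature combined group (2^24 - 1
      # subsets) is not affordable; search the union of the parameters in
      # the best internal and best external classifiers instead.
      union_cols <- unique(c(strsplit(res$internal$best$features, "+",
                                      fixed = TRUE)[[1]],
                             strsplit(res$external$best$features, "+",
                                      fixed = TRUE)[[1]]))
      if (length(union_cols) > 16L) union_cols <- union_cols[1:16]
      res$combined <- exhaustive_search(features, columns = union_cols,
                                        k = config$k,
                                        metrics = config$metrics)
      res
    })

  comparison <- compare_groups(search$internal, search$external)

  summary <- list(
    n_lesions = nrow(features),
    n_benign = sum(features$label == "benign"),
    n_malignant = sum(features$label == "malignant"),
    n_subsets_per_group = search$internal$n_subsets,
    best = lapply(search, function(s) {
      list(features = s$best$features, auc = s$best$auc)
    }),
    delta_auc = list(n_internal_wins = comparison$n_internal_wins,
                     n_subsets = comparison$n_subsets,
                     mean = mean(comparison$table$delta_auc)))

  list(features = features, search = search, comparison = comparison,
       summary = summary)
}

#' Estimate phantom correction curves for all parameters
#'
#' Builds the twelve parametric maps of a homogeneous reference-phantom
#' frame over full-image sliding windows and derives one depth-correction
#' curve per parameter.
#'
#' @param phantom an [rf_frame()] from [make_reference_phantom()] or a
#'   real phantom acquisition.
#' @param mode `"multiplicative"` or `"additive"`.
#' @inheritParams extract_features
#' @param params parameters to correct (default all twelve).
#' @return Named list of `correction_curve`s.
#' @export
phantom_correction_curves <- function(phantom,
                                      mode = c("multiplicative",
                                               "additive"),
                                      window_mm = 1, overlap = 0.92,
                                      db_range = c(20, 100), levels = 20L,
                                      displacement_mm = 0.3,
                                      entropy_bins = 40L,
                                      params = QUS_PARAMS) {
  mode <- match.arg(mode)
  env <- detect_envelope(phantom)
  bm <- log_compress(env, db_range)
  windows <- place_windows(dim(env$values), env$pixel_mm, window_mm,
                           overlap)
  curves <- lapply(params, function(pp) {
    img <- if (pp %in% c("NAK", "ENT")) env else bm
    map <- build_parametric_map(img, windows, pp,
                                entropy_bins = entropy_bins,
                                displacement_mm = displacement_mm,
                                levels = levels)
    estimate_correction_curve(map, mode = mode)
  })
  stats::setNames(curves, params)
}
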