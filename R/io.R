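# Plain-text serialization. An RF frame is stored as a directory bundle:
# rf.tsv (tab-separated sample matrix) plus meta.json carrying fs_hz,
# line_pitch_mm and sound_speed_mps. (The environment has no HDF5-capable
# R package; the logical datasets are the same.)

#' Write / read an RF frame bundle
#'
#' @param frame an [rf_frame()].
#' @param dir directory to create/fill (rf.tsv + meta.json).
#' @return `read_rf_frame` returns an [rf_frame()].
#' @export
write_rf_frame <- function(frame, dir) {
  stopifnot(inherits(frame, "rf_frame"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(frame$samples, file.path(dir, "rf.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs_hz = frame$fs_hz,
                            line_pitch_mm = frame$line_pitch_mm,
                            sound_speed_mps = frame$sound_speed_mps),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  samples <- as.matrix(utils::read.table(file.path(dir, "rf.tsv"),
                                         sep = "\t"))
  dimnames(samples) <- NULL
  rf_frame(samples, meta$fs_hz, meta$line_pitch_mm, meta$sound_speed_mps)
}

#' Write / read a lesion contour as JSON
#'
#' Contours are closed polygons stored as a list of `[x_mm, z_mm]`
#' vertices (last vertex repeats the first).
#'
#' @param contour `n x 2` matrix.
#' @param path JSON file path.
#' @return `read_contour` returns the vertex matrix.
#' @export
write_contour <- function(contour, path) {
  jsonlite::write_json(apply(unname(as.matrix(contour)), 1L, identity,
                             simplify = FALSE),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  poly <- if (is.list(v)) do.call(rbind, v) else v
  colnames(poly) <- c("x_mm", "z_mm")
  poly
}

#' Write / read per-lesion class labels as CSV
#'
#' @param labels data frame with columns `lesion_id`, `label`.
#' @param path CSV file path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("lesion_id", "label") %in% names(labels)),
            all(labels$label %in% c("benign", "malignant")))
  write.csv(labels[, c("lesion_id", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a feature table as CSV
#'
#' Fixed column order: `lesion_id`, `label`, the twelve internal features,
#' then the twelve external features.
#'
#' @param table feature table from [extract_features()].
#' @param path CSV file path.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("lesion_id", "label", paste0(QUS_PARAMS, "_int"),
            paste0(QUS_PARAMS, "_ext"))
  stopifnot(all(cols %in% names(table)))
  write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Run-length encode / decode an ROI mask as JSON
#'
#' @param mask a `roi_mask`.
#' @param path JSON file path.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  r <- rle(as.vector(mask$mask))
  jsonlite::write_json(list(shape = dim(mask$mask), kind = mask$kind,
                            pixel_mm = mask$pixel_mm,
                            lengths = r$lengths, values = r$values),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- inverse.rle(structure(list(lengths = obj$lengths,
                                  values = obj$values), class = "rle"))
  roi_mask(matrix(v, obj$shape[1L], obj$shape[2L]), obj$kind,
           obj$pixel_mm)
}

#' Write a correction curve as CSV
#'
#' @param curve a `correction_curve`.
#' @param path CSV path (columns depth_mm, factor, parameter, mode).
#' @export
write_correction_curve <- function(curve, path) {
  write.csv(data.frame(depth_mm = curve$depth_mm, factor = curve$factor,
                       parameter = curve$parameter, mode = curve$mode),
            path, row.names = FALSE)
  invisible(path)
}

#' Write the pipeline report bundle
#'
#' Emits the feature table and per-group subset reports as CSV and the
#' machine-readable summary as JSON.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(result$features, file.path(dir, "features.csv"))
  for (g in names(result$search)) {
    write.csv(result$search[[g]]$reports,
              file.path(dir, sprintf("search_%s.csv", g)),
              row.names = FALSE)
  }
  write.csv(result$comparison$table, file.path(dir, "delta_auc.csv"),
            row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write / read a cohort bundle to a directory tree
#'
#' Per lesion: one subdirectory holding the two RF-frame bundles and the
#' contour JSON; labels.csv at the root.
#'
#' @param cohort a `qus_cohort` (frames are materialized on write).
#' @param dir target directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labels(cohort$labels, file.path(dir, "labels.csv"))
  for (i in seq_along(cohort$lesions)) {
    les <- cohort$lesions[[i]]
    ldir <- file.path(dir, les$lesion_id)
    dir.create(ldir, showWarnings = FALSE)
    frames <- lesion_frames(cohort, i)
    for (p in seq_along(frames)) {
      write_rf_frame(frames[[p]], file.path(ldir, sprintf("plane%d", p)))
    }
    write_contour(les$contour, file.path(ldir, "contour.json"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  labels <- read_labels(file.path(dir, "labels.csv"))
  lesions <- lapply(seq_len(nrow(labels)), function(i) {
    ldir <- file.path(dir, labels$lesion_id[i])
    planes <- sort(list.dirs(ldir, recursive = FALSE))
    list(lesion_id = labels$lesion_id[i], label = labels$label[i],
         contour = read_contour(file.path(ldir, "contour.json")),
         frames = lapply(planes, read_rf_frame))
  })
  structure(list(lesions = lesions, labels = labels, spec = NULL),
            class = "qus_cohort")
}
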