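#' @title Plain-text input/output
#'
#' @description
#' On-disk interchange formats for every stage: one CSV per subject
#' (rows = time points, columns = ROIs) with a JSON sidecar carrying the
#' label and sampling interval; per-window connectivity matrices as
#' ROI-labeled CSV; and the vectorized feature dataset as a feature CSV,
#' a label CSV and a JSON metadata sidecar.
#'
#' @name io
NULL

#' Write a cohort to a directory (CSV + JSON sidecar per subject)
#'
#' @param cohort list of `bold_ts` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the written CSV paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort, function(ts) {
    csv <- file.path(dir, paste0(ts$subject_id, ".csv"))
    utils::write.csv(ts$values, csv, row.names = FALSE)
    jsonlite::write_json(
      list(subject_id = ts$subject_id, group = ts$group,
           sampling_interval = ts$sampling_interval),
      file.path(dir, paste0(ts$subject_id, ".json")), auto_unbox = TRUE)
    csv
  }, character(1))
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `<subject>.csv` / `<subject>.json` pairs.
#' @return list of `bold_ts` objects, in filename order.
#' @export
read_cohort <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(sidecars) == 0) abort_input("no subject sidecars found in ", dir)
  lapply(sidecars, function(js) {
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    vals <- as.matrix(utils::read.csv(sub("\\.json$", ".csv", js),
                                      check.names = FALSE))
    structure(list(values = vals,
                   sampling_interval = meta$sampling_interval,
                   group = meta$group, subject_id = meta$subject_id),
              class = "bold_ts")
  })
}

#' Write a connectivity matrix as ROI-labeled CSV
#'
#' @param m a `conn_matrix`.
#' @param path output file.
#' @export
write_conn_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  df <- as.data.frame(m$values)
  utils::write.csv(cbind(ROI = m$roi_labels, df), path, row.names = FALSE)
  invisible(path)
}

#' Write a feature dataset (features CSV + labels CSV + JSON metadata)
#'
#' @param dataset a `feature_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "feature_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(subject_id = dataset$subject_ids,
               window_index = dataset$window_ids,
               label = as.character(dataset$labels)),
    file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cfg = unclass(dataset$cfg), seed = dataset$seed,
         n_rows = nrow(dataset$features), n_features = ncol(dataset$features)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a feature dataset written by [write_dataset()]
#'
#' The connectivity matrices themselves are not round-tripped; the
#' returned object carries the vectorized features and labels, which is
#' what the evaluation harness consumes.
#'
#' @param dir directory written by [write_dataset()].
#' @return a `feature_dataset` (without the `matrices` field).
#' @export
read_dataset <- function(dir) {
  feats <- as.matrix(utils::read.csv(file.path(dir, "features.csv"),
                                     check.names = FALSE))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  structure(list(features = feats, labels = factor(lab$label),
                 feature_names = colnames(feats),
                 subject_ids = lab$subject_id, window_ids = lab$window_index,
                 matrices = NULL,
                 cfg = do.call(te_config, meta$cfg[c("tau", "window_seconds",
                                                     "stride_seconds",
                                                     "binarize_threshold")]),
                 seed = meta$seed),
            class = "feature_dataset")
}
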