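# Container and table export.

#' Save or load a trial container
#'
#' Trial sets, mapping sets and time-frequency tensors are stored as a
#' single RDS container holding the arrays together with their metadata
#' (sampling rate, onset index, seed, labels).
#'
#' @param x object to save.
#' @param path file path.
#' @return `load_trialset` returns the stored object.
#' @export
save_trialset <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_trialset
#' @export
load_trialset <- function(path) readRDS(path)

#' Export ground-truth and label tables as CSV
#'
#' Writes the condition table, the per-electrode ground-truth ERF table and
#' the trial label table of a synthetic data set to a directory.
#'
#' @param truth an `efp_truth` object.
#' @param trials optional `efp_trials` object (labels are exported too).
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
export_truth_csv <- function(truth, trials = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    conditions = file.path(dir, "conditions.csv"),
    erfs = file.path(dir, "ground_truth_erfs.csv"),
    geometry = file.path(dir, "array_geometry.csv")
  )
  utils::write.csv(truth$conditions, paths["conditions"], row.names = FALSE)
  utils::write.csv(truth$erfs, paths["erfs"], row.names = FALSE)
  utils::write.csv(as.data.frame(truth$geometry), paths["geometry"], row.names = FALSE)
  if (!is.null(trials)) {
    paths <- c(paths, labels = file.path(dir, "trial_labels.csv"))
    utils::write.csv(trials$trials, paths["labels"], row.names = FALSE)
  }
  invisible(paths)
}

#' Write selected time-frequency windows to JSON
#'
#' @param windows named list of `efp_window` objects.
#' @param path output file.
#' @export
write_windows_json <- function(windows, path) {
  jsonlite::write_json(
    lapply(windows, function(w) w[c("category", "t0", "t1", "f0", "f1", "provenance")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read time-frequency windows from JSON
#'
#' @param path JSON file written by [write_windows_json()].
#' @return named list of `efp_window` objects.
#' @export
read_windows_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(w) structure(as.list(w), class = "efp_window"))
}
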