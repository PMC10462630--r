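#' Write / read an ECG record as CSV plus JSON sidecar
#'
#' The CSV holds `time_s` and the 12 lead columns; the sidecar
#' (`<record_id>.json`) holds labels, sampling rate, duration and seed.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the CSV path.
#' @export
write_ecg_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(record$leads[[1]])
  df <- tibble::as_tibble(c(list(time_s = (seq_len(n) - 1) / record$fs),
                            record$leads))
  csv <- file.path(dir, paste0(record$record_id, ".csv"))
  readr::write_csv(df, csv)
  side <- list(record_id = record$record_id, fs = record$fs,
               duration_s = record$duration_s, seed = record$seed,
               labels = as.list(record$labels))
  jsonlite::write_json(side, file.path(dir, paste0(record$record_id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' @rdname write_ecg_record
#' @param csv_path Path to a record CSV written by [write_ecg_record()].
#' @export
read_ecg_record <- function(csv_path) {
  df <- readr::read_csv(csv_path, show_col_types = FALSE)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path),
                              simplifyVector = TRUE)
  leads <- purrr::map(as.list(df[ECG_LEADS]), as.numeric)
  structure(
    list(record_id = side$record_id, leads = leads, fs = side$fs,
         duration_s = side$duration_s,
         labels = unlist(side$labels), seed = as.integer(side$seed)),
    class = "ecg_record"
  )
}

#' Write a dataset of records with a manifest
#'
#' @param records List of `ecg_record`s.
#' @param dir Output directory.
#' @return The manifest tibble (also written to `manifest.csv`), invisibly.
#' @export
write_ecg_dataset <- function(records, dir) {
  paths <- purrr::map_chr(records, write_ecg_record, dir = dir)
  manifest <- dataset_manifest(records, paths)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
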