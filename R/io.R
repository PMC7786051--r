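# File formats at the pipeline boundaries: CSV tables (tracks, truth,
# results, comparison; UTF-8, "." decimal, header row), a JSON QC report,
# YAML run configuration, and multi-page grayscale TIFF frame input.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop_data(sprintf("input file not found: %s", path),
              class = "spherofall_missing_input")
  }
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop_invalid(sprintf("%s lacks required column(s): %s", basename(path),
                         paste(missing_cols, collapse = ", ")))
  }
  tbl
}

#' Read / write position tracks (tracks.csv schema)
#'
#' Columns: `spheroid_id`, `repetition`, `frame`, `time_s`, `row_px`,
#' `col_px`, `radius_px`, `quality`.
#'
#' @param path CSV path.
#' @param tracks Data frame in the schema.
#' @return `read_tracks_csv` returns the data frame; `write_tracks_csv`
#'   returns `path` invisibly.
#' @export
read_tracks_csv <- function(path) {
  read_csv_checked(path, c("spheroid_id", "repetition", "frame", "row_px",
                           "radius_px"))
}

#' @rdname read_tracks_csv
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ground-truth tables (truth.csv schema)
#'
#' Columns: `spheroid_id`, `condition`, `r_um_true`, `rho_fg_um3_true`,
#' `weight_ng_true`, `v_um_s_true`.
#'
#' @param path CSV path.
#' @param truth Data frame in the schema.
#' @return The data frame, or `path` invisibly on write.
#' @export
read_truth_csv <- function(path) {
  read_csv_checked(path, c("spheroid_id", "r_um_true", "rho_fg_um3_true"))
}

#' @rdname read_truth_csv
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-spheroid results (results.csv schema)
#'
#' Schema as produced by [results_table()].
#'
#' @param path CSV path.
#' @param results Data frame in the schema.
#' @return The data frame, or `path` invisibly on write.
#' @export
read_results_csv <- function(path) {
  read_csv_checked(path, c("spheroid_id", "condition", "diameter_um",
                           "velocity_um_s", "mass_density_fg_um3",
                           "weight_ng"))
}

#' @rdname read_results_csv
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the cohort QC report as JSON
#'
#' Serialises per-metric Shapiro-Wilk results before/after removal, the
#' Tukey fences of screened metrics, and the outlier ledger.
#'
#' @param qc A `cohort_qc` object or a named list of them (per condition).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  as_report <- function(q) {
    list(
      n_before = q$n_before, n_after = q$n_after, alpha = q$alpha,
      force_screen = q$force_screen,
      shapiro_before = q$shapiro_before, shapiro_after = q$shapiro_after,
      fences = q$fences, removed = as.list(q$removed),
      ledger = q$ledger
    )
  }
  payload <- if (inherits(qc, "cohort_qc")) as_report(qc) else
    lapply(qc, as_report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write the cohort-comparison table (comparison.csv schema)
#'
#' @param comparison Data frame from [compare_all_metrics()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF (or a directory of numbered frames)
#'
#' @param path A multi-page grayscale TIFF file, or a directory whose
#'   `.tif`/`.tiff` files sort into frame order.
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @return A [frame_sequence()].
#' @export
read_frames_tiff <- function(path, pixel_size, frame_interval) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- a[, , 1] # first channel of RGB(A)
    matrix(as.numeric(a), nrow(a), ncol(a))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) {
      stop_data(sprintf("no TIFF frames found in %s", path),
                class = "spherofall_missing_input")
    }
    frames <- lapply(files, function(f) to_gray(tiff::readTIFF(f)))
  } else {
    if (!file.exists(path)) {
      stop_data(sprintf("input file not found: %s", path),
                class = "spherofall_missing_input")
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray)
  }
  frame_sequence(frames, pixel_size, frame_interval)
}

#' Write a frame sequence as a multi-page TIFF
#'
#' @param sequence A [frame_sequence()].
#' @param path Output TIFF path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(sequence, path, bits_per_sample = 8) {
  if (!inherits(sequence, "frame_sequence")) {
    stop_invalid("sequence must be a frame_sequence")
  }
  tiff::writeTIFF(sequence$frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}
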