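#' Read a grayscale image (TIFF or PNG)
#'
#' @param path file path; format inferred from the extension.
#' @return Numeric matrix with intensities in \[0, 1\].  Multi-channel
#'   images are averaged to grayscale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_spec("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_spec("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale image as 16-bit TIFF
#'
#' @param image numeric matrix; values are clamped to \[0, 1\].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as.matrix(image)
  image[image < 0] <- 0
  image[image > 1] <- 1
  tiff::writeTIFF(image, path, bits.per.sample = 16L)
  invisible(path)
}

read_csv_checked <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) stop_spec("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_spec("malformed header in ", path, ": missing column(s) ",
              paste(missing, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    bad <- which(is.na(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stop_spec("non-numeric or missing '", col, "' in ", path,
                " at data row ", bad[1L])
    }
    df[[col]] <- as.numeric(v)
  }
  df
}

#' Read an eye-angle trace from CSV (with optional YAML metadata)
#'
#' @param path CSV with columns `time_s`, `angle_deg`.
#' @param meta_path YAML sidecar with `drum_velocity_dps`, optional
#'   `spatial_frequency_cpd` and `direction`; defaults to `<path>.yaml`
#'   when present.
#' @return An `eye_trace` list usable by [detect_fast_phases()].
#' @export
read_eye_trace <- function(path, meta_path = paste0(path, ".yaml")) {
  df <- read_csv_checked(path, c("time_s", "angle_deg"))
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(meta$drum_velocity_dps)) {
    stop_spec("trace metadata must provide 'drum_velocity_dps' (", meta_path, ")")
  }
  structure(list(time_s = df$time_s, angle_deg = df$angle_deg,
                 drum_velocity_dps = meta$drum_velocity_dps,
                 spatial_frequency_cpd = meta$spatial_frequency_cpd,
                 direction = meta$direction),
            class = "eye_trace")
}

#' Write an eye-angle trace to CSV plus YAML metadata
#'
#' @param trace an `eye_trace`.
#' @param path output CSV path; metadata goes to `<path>.yaml`.
#' @return The path, invisibly.
#' @export
write_eye_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              angle_deg = trace$angle_deg),
                   path, row.names = FALSE)
  yaml::write_yaml(list(drum_velocity_dps = trace$drum_velocity_dps,
                        spatial_frequency_cpd = trace$spatial_frequency_cpd,
                        direction = trace$direction),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read an ERG voltage trace from CSV (with YAML metadata)
#'
#' @param path CSV with columns `time_ms`, `voltage_uv`.
#' @param meta_path YAML sidecar providing `onsets_ms` (required) and
#'   optionally `stimulus_ms`, `body_length_mm`.
#' @return An `erg_trace` list usable by [baseline_correct()].
#' @export
read_erg_trace <- function(path, meta_path = paste0(path, ".yaml")) {
  df <- read_csv_checked(path, c("time_ms", "voltage_uv"))
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (is.null(meta$onsets_ms)) {
    stop_spec("ERG metadata must provide 'onsets_ms' (", meta_path, ")")
  }
  structure(list(time_ms = df$time_ms, voltage_uv = df$voltage_uv,
                 onsets_ms = as.numeric(meta$onsets_ms),
                 stimulus_ms = meta$stimulus_ms,
                 body_length_mm = meta$body_length_mm),
            class = "erg_trace")
}

#' Write an ERG trace to CSV plus YAML metadata
#' @param trace an `erg_trace`.
#' @param path output CSV path; metadata goes to `<path>.yaml`.
#' @return The path, invisibly.
#' @export
write_erg_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time_ms,
                              voltage_uv = trace$voltage_uv),
                   path, row.names = FALSE)
  yaml::write_yaml(list(onsets_ms = as.numeric(trace$onsets_ms),
                        stimulus_ms = trace$stimulus_ms),
                   paste0(path, ".yaml"))
  invisible(path)
}

COHORT_COLS <- c("fish_id", "genotype", "eye", "age", "body_length_mm",
                 "outcome", "value")

#' Read a long-format cohort table from CSV
#'
#' @param path CSV with columns `fish_id`, `genotype`, `eye`, `age`,
#'   `body_length_mm`, `outcome`, `value`.  Numeric columns are validated
#'   cell by cell and errors name the offending row.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort <- function(path) {
  df <- read_csv_checked(path, COHORT_COLS,
                         numeric_cols = c("body_length_mm", "value"))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV with a fixed column order
#' @param table a cohort table.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(all(COHORT_COLS %in% names(table)))
  utils::write.csv(table[COHORT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Write a results table deterministically (CSV and JSON)
#'
#' @param results a data.frame.
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return The CSV path, invisibly.
#' @export
write_results <- function(results, path) {
  csv <- paste0(path, ".csv")
  utils::write.csv(results, csv, row.names = FALSE)
  jsonlite::write_json(results, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}
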