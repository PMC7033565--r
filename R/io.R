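#' Read a reflectance CSV with schema validation
#'
#' Expects the columns `plot_id`, `date`, `green`, `red`, `red_edge`,
#' `nir` (plus optional `cultivar`, `treatment`). Dates must be ISO-8601.
#' Records with a negative band are rejected at ingest: they are flagged
#' and excluded, and the count is reported, rather than clamped (clamping
#' would fabricate ratios).
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return data.frame of valid reflectance records; excluded rows are
#'   attached as attribute `"rejected"`.
#' @export
read_reflectance_csv <- function(path) {
  df <- read_table_checked(path,
                           required = c("plot_id", "date", "green", "red",
                                        "red_edge", "nir"),
                           numeric_cols = c("green", "red", "red_edge", "nir"))
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) {
    stop("schema violation in ", path, ": column 'date' must be ISO-8601",
         call. = FALSE)
  }
  bands <- as.matrix(df[, .bands])
  bad <- apply(!is.finite(bands) | bands < 0, 1, any)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- df[bad, , drop = FALSE]
  if (any(bad)) {
    message("read_reflectance_csv: rejected ", sum(bad),
            " record(s) with negative or non-finite reflectance")
  }
  out
}

#' Read a SPAD trial CSV with schema validation
#'
#' @param path CSV with columns `plot_id`, `thermal_time`, `layer`,
#'   `spad`, `area_fraction`.
#' @return data.frame.
#' @export
read_spad_csv <- function(path) {
  read_table_checked(path,
                     required = c("plot_id", "thermal_time", "layer",
                                  "spad", "area_fraction"),
                     numeric_cols = c("thermal_time", "spad",
                                      "area_fraction"))
}

#' Read a CSV and verify its schema
#'
#' @param path file path.
#' @param required required column names.
#' @param numeric_cols columns that must parse as finite numerics.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("schema violation in ", path, ": column '", col,
           "' is not numeric (first bad row: ",
           if (is.na(bad_row)) "type" else bad_row, ")", call. = FALSE)
    }
  }
  df
}

#' Write a table as UTF-8 CSV (deterministic formatting)
#'
#' @param data data.frame.
#' @param path output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(data, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(data, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension) and merges it
#' over the package defaults. The effective configuration carries the
#' seed, class-scheme edges, cleaning threshold, CV settings and
#' senescence/season options used by the analysis scripts, and can be
#' written back next to a run's outputs for provenance.
#'
#' @param path optional path to a `.yaml`/`.yml`/`.json` file; omit for
#'   the defaults.
#' @param overrides optional named list merged last.
#' @return named list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 20170404,
    cleaning_max_gai = 7,
    class_breaks = c(0, 0.25, 2, 3, 4, 5, Inf),
    cv_folds = 10,
    cv_selection_metric = "rmse",
    senescence = list(onset_date = "2017-06-19", base_temp = 0,
                      spad_calibration = c(a = 0.06, b = 0.04)),
    season = list(anchor_sowing = NULL, clip_zero = FALSE))
  cfg <- defaults
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
                   yaml = , yml = yaml::read_yaml(path),
                   json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                   stop("unsupported config format: .", ext, call. = FALSE))
    cfg <- modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("config field 'seed' must be an integer", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write the effective configuration next to a run's outputs
#'
#' @param config a [run_config()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}
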