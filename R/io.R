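# CSV readers/writers and structured run configuration. All record files
# share one convention: `#`-prefixed metadata header lines (`# fs=<Hz>`
# mandatory), then a column-name line, then the data.

fv_meta_header <- function(fs, extra = NULL) {
  c(sprintf("# fs=%.10g", fs),
    if (length(extra)) sprintf("# %s=%s", names(extra),
                               vapply(extra, format, character(1))))
}

parse_meta <- function(path, stage) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.+)\\s*$", meta_lines))
  kv <- Filter(function(x) length(x) == 3L, kv)
  meta <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  if (is.null(meta$fs))
    fv_stop(stage, "format-error",
            sprintf("missing '# fs=<Hz>' header in %s", path))
  meta$fs <- as.numeric(meta$fs)
  if (!is.finite(meta$fs) || meta$fs <= 0)
    fv_stop(stage, "format-error", "header fs is not a positive number")
  meta
}

read_table_checked <- function(path, expected_cols, stage) {
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) fv_stop(stage, "parse-error",
                                sprintf("%s: %s", path, conditionMessage(e)))
  )
  missing <- setdiff(expected_cols, names(df))
  if (length(missing))
    fv_stop(stage, "format-error",
            sprintf("%s lacks column(s): %s", path,
                    paste(missing, collapse = ", ")))
  for (col in expected_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      fv_stop(stage, "parse-error",
              sprintf("%s: non-numeric or missing '%s' at data line %d",
                      path, col, bad[1]))
    df[[col]] <- v
  }
  df
}

#' Write a coupler record to CSV
#'
#' Format: `# fs=<Hz>` metadata header (plus any `extra` key=value lines),
#' then columns `t,u1,u2,u3`.
#'
#' @param record A [coupler_record()].
#' @param path Output file path.
#' @param extra Optional named list written as additional `# key=value`
#'   metadata lines (e.g. seed and simulation truths).
#' @return `path`, invisibly.
#' @export
write_coupler_csv <- function(record, path, extra = NULL) {
  stopifnot(inherits(record, "coupler_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fv_meta_header(record$fs, extra), con)
  writeLines("t,u1,u2,u3", con)
  t <- time_axis(record)
  writeLines(sprintf("%.10g,%.10g,%.10g,%.10g",
                     t, record$u[, 1], record$u[, 2], record$u[, 3]), con)
  invisible(path)
}

#' Read a coupler record from CSV
#' @param path File written by [write_coupler_csv()].
#' @return A [coupler_record()]; header metadata is attached as attribute
#'   `meta`.
#' @export
read_coupler_csv <- function(path) {
  meta <- parse_meta(path, "io")
  df <- read_table_checked(path, c("t", "u1", "u2", "u3"), "io")
  rec <- coupler_record(as.matrix(df[c("u1", "u2", "u3")]),
                        fs = meta$fs, t0 = df$t[1])
  attr(rec, "meta") <- meta
  rec
}

#' Write a phase series to CSV (`t,phase_rad` with `# fs=` header)
#' @param phase A [phase_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phase_csv <- function(phase, path) {
  stopifnot(inherits(phase, "phase_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fv_meta_header(phase$fs), con)
  writeLines("t,phase_rad", con)
  writeLines(sprintf("%.10g,%.10g", time_axis(phase), phase$values), con)
  invisible(path)
}

#' Read a phase series from CSV
#' @param path File written by [write_phase_csv()].
#' @return A [phase_series()].
#' @export
read_phase_csv <- function(path) {
  meta <- parse_meta(path, "io")
  df <- read_table_checked(path, c("t", "phase_rad"), "io")
  phase_series(df$phase_rad, fs = meta$fs, t0 = df$t[1])
}

#' Write a per-minute vitals table to CSV
#' @param vt A `vitals_table` from [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vitals_csv <- function(vt, path) {
  stopifnot(inherits(vt, "vitals_table"))
  out <- data.frame(minute = vt$minute, rr_bpm = vt$rr_bpm,
                    hr_bpm = vt$hr_bpm, valid_rr = vt$valid_rr,
                    valid_hr = vt$valid_hr, distorted = vt$distorted)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one spectrum frame to CSV (`freq_hz,magnitude`)
#' @param spec A `spectrum_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_frame"))
  utils::write.csv(data.frame(freq_hz = spec$freqs, magnitude = spec$mags),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format paired-measurements CSV
#'
#' Expected columns: `subject,sex,weight_kg,vital,minute,reference,efos`.
#'
#' @param path Input file path.
#' @return A `paired_measurements` data frame.
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    fv_stop("io", "format-error", sprintf("empty or missing file: %s", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) fv_stop("io", "parse-error",
                                sprintf("%s: %s", path, conditionMessage(e)))
  )
  need <- c("subject", "sex", "weight_kg", "vital", "minute",
            "reference", "efos")
  missing <- setdiff(need, names(df))
  if (length(missing))
    fv_stop("io", "format-error",
            sprintf("%s lacks column(s): %s", path,
                    paste(missing, collapse = ", ")))
  class(df) <- c("paired_measurements", "data.frame")
  df
}

#' Write a paired-measurements table to CSV
#' @param pairs A `paired_measurements` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a structured run configuration
#'
#' A flat YAML file whose keys mirror the [sampling_spec()],
#' [physio_params()], [coupler_params()] and [band_config()] argument
#' names, plus optional `seed`. Missing keys take the package defaults.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return A list of class `run_config` with components `sampling`,
#'   `physio`, `coupler`, `band`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path))
      fv_stop("io", "format-error", sprintf("config not found: %s", path))
    yaml::read_yaml(path) %||% list()
  }
  pick <- function(fn) {
    args <- raw[intersect(names(raw), names(formals(fn)))]
    do.call(fn, args)
  }
  structure(list(sampling = pick(sampling_spec),
                 physio = pick(physio_params),
                 coupler = pick(coupler_params),
                 band = pick(band_config),
                 seed = raw$seed %||% NULL),
            class = "run_config")
}
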