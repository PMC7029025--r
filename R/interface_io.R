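# Readers, writers and run configuration: peak-list CSV, MGF spectra,
# family reports (JSON + CSV) and the flat key-value config file.

#' Read an MS1 peak-list CSV
#'
#' Expects a header with columns `rt_min`, `mz`, `intensity` and optionally
#' `id`; missing ids are generated from the row index. Non-numeric cells
#' are reported with their row and column.
#'
#' @param path Path to the CSV file.
#' @return A [peak_list()].
#' @examples
#' read_peaklist(system.file("extdata", "table1_peaks.csv",
#'                           package = "lipoladder"))
#' @export
read_peaklist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("rt_min", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak-list file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in column '%s', row %d", col,
                   if (length(bad)) bad[1] else which(is.na(v))[1]),
           call. = FALSE)
    df[[col]] <- v
  }
  peak_list(rt = df$rt_min, mz = df$mz, intensity = df$intensity,
            id = if ("id" %in% names(df)) df$id else NULL)
}

#' Write a peak list as CSV
#'
#' @param peaks A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  peaks <- peak_list(peaks)
  utils::write.csv(peaks[, c("rt_min", "mz", "intensity", "id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS2 spectra from an MGF file
#'
#' Minimal MGF dialect: `BEGIN IONS` / `END IONS` blocks with a `PEPMASS=`
#' line, optional `TITLE=` and `RTINSECONDS=`, and whitespace-separated
#' `mz intensity` peak lines. Blocks without a parseable PEPMASS are
#' skipped with a warning.
#'
#' @param path Path to the MGF file.
#' @return List of spectra, each a list with `precursor_mz`, `rt_s` (NA if
#'   absent), `title` (NA if absent) and `peaks` (data frame `mz`,
#'   `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      pep <- NA_real_; rts <- NA_real_; title <- NA_character_
      mzv <- numeric(); inv <- numeric()
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "PEPMASS=")) {
          pep <- suppressWarnings(
            as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]][1]))
        } else if (startsWith(ln, "RTINSECONDS=")) {
          rts <- suppressWarnings(as.numeric(sub("^RTINSECONDS=", "", ln)))
        } else if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (nzchar(ln) && !grepl("=", ln, fixed = TRUE)) {
          parts <- strsplit(ln, "[ \t]+")[[1]]
          m <- suppressWarnings(as.numeric(parts[1]))
          it <- if (length(parts) >= 2)
            suppressWarnings(as.numeric(parts[2])) else 1
          if (!is.na(m)) { mzv <- c(mzv, m); inv <- c(inv, it) }
        }
        i <- i + 1L
      }
      if (is.na(pep)) {
        warning("skipping MGF block without a valid PEPMASS", call. = FALSE)
      } else {
        spectra[[length(spectra) + 1L]] <- list(
          precursor_mz = pep, rt_s = rts, title = title,
          peaks = data.frame(mz = mzv, intensity = inv))
      }
    }
    i <- i + 1L
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra List of spectra as returned by [read_mgf()] or
#'   [simulate_ms2()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title))
      writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.null(sp$rt_s) && !is.na(sp$rt_s))
      writeLines(sprintf("RTINSECONDS=%.3f", sp$rt_s), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

.run_config_defaults <- function() {
  list(ch2_tol = 0.03, water_tol = 0.03, frag_tol = 0.05, daughter_tol = 0.2,
       ppm_window = 30, anchor_mz = NA_real_, anchor_carbons = NA_integer_,
       seed = NA_integer_, verbosity = "info")
}

#' Build a run configuration
#'
#' Flat key-value configuration for pipeline runs: edge and fragment
#' tolerances (Da), the composition ppm window, the tail-length anchor and
#' the seed. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults, see
#'   `lipoladder:::.run_config_defaults()`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- .run_config_defaults()
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, override)
  for (key in c("ch2_tol", "water_tol", "frag_tol", "daughter_tol", "ppm_window"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0)
      stop("config key '", key, "' must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML key-value file
#'
#' @param path Path to a flat YAML file of `key: value` pairs.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly. `read_run_config(write_run_config(cfg, p))`
#'   is the identity.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, function(v) length(v) == 1 && is.na(v), TRUE)]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write an annotated family report
#'
#' Writes the full evidence trail as JSON (members, edges, anchor,
#' warnings) and a flat CSV with one row per member (designation,
#' retention time, protonated mass, type, tail carbons, nominal offset).
#' Output field order is fixed, so a rerun on the same input is
#' byte-identical.
#'
#' @param family An annotated `isoform_family`.
#' @param json_path Path for the JSON report (NULL to skip).
#' @param csv_path Path for the CSV report (NULL to skip).
#' @return Invisible list of the paths written.
#' @export
write_report <- function(family, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(family, "isoform_family"))
  written <- list()
  if (!is.null(json_path)) {
    payload <- list(
      members = family$members,
      edges = family$edges,
      anchor = family$anchor,
      warnings = as.list(family$warnings))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written$json <- json_path
  }
  if (!is.null(csv_path)) {
    utils::write.csv(family_report(family), csv_path, row.names = FALSE,
                     quote = FALSE)
    written$csv <- csv_path
  }
  invisible(written)
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` (e.g.
#'   `"table1_peaks.csv"`); with no argument, lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
lipoladder_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "lipoladder")))
  .extdata(file)
}
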