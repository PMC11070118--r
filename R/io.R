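#' Construct a raw spectrum
#'
#' A raw spectrum is the unprocessed spectrometer readout: detector counts on
#' a strictly increasing wavelength grid, optionally tagged with the subject
#' it came from, its tissue class, and an acquisition timestamp.
#'
#' @param wavelengths Strictly increasing numeric vector, nm.
#' @param intensities Finite numeric vector of detector counts, same length.
#' @param subject_id Optional subject identifier (string).
#' @param class_label Optional class label (see [tissue_classes()]).
#' @param timestamp_s Optional acquisition time in seconds.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(wavelengths, intensities, subject_id = NA_character_,
                         class_label = NA_character_, timestamp_s = NA_real_) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  ns_assert(length(wavelengths) == length(intensities),
            "wavelengths and intensities differ in length", "parse_error")
  ns_assert(length(wavelengths) > 0, "empty spectrum", "parse_error")
  ns_assert(!is.unsorted(wavelengths, strictly = TRUE),
            "wavelengths must be strictly increasing", "parse_error")
  ns_assert(all(is.finite(intensities)), "non-finite intensities", "parse_error")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 subject_id = as.character(subject_id),
                 class_label = as.character(class_label),
                 timestamp_s = as.numeric(timestamp_s)),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("Raw spectrum: %d points, %.1f-%.1f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  if (!is.na(x$class_label)) cat("  class:  ", x$class_label, "\n")
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Construct a calibration pair
#'
#' Holds the white-standard and dark/noise reference spectra used to convert
#' raw counts to relative intensity. Both must share the grid of the spectra
#' they calibrate, and `standard - noise` must be nonzero at every
#' wavelength.
#'
#' @param wavelengths Shared wavelength grid, nm.
#' @param standard White-standard counts (reference reflector).
#' @param noise Dark/instrument-background counts.
#' @return An object of class `calibration_pair`.
#' @export
calibration_pair <- function(wavelengths, standard, noise) {
  wavelengths <- as.numeric(wavelengths)
  standard <- as.numeric(standard)
  noise <- as.numeric(noise)
  ns_assert(length(wavelengths) == length(standard) &&
              length(standard) == length(noise),
            "calibration vectors differ in length", "parse_error")
  ns_assert(all(is.finite(standard)) && all(is.finite(noise)),
            "non-finite calibration values", "parse_error")
  structure(list(wavelengths = wavelengths, standard = standard, noise = noise),
            class = "calibration_pair")
}

#' Read a spectrum from a two-column delimited text file
#'
#' Accepts the spectrometer-export-like dialect written by
#' [write_spectrum()]: lines beginning with `#` are comments (metadata
#' comments of the form `# key: value` are parsed back into the spectrum),
#' data lines carry wavelength and intensity separated by tabs, commas or
#' whitespace. Wavelengths are always nm; no unit autodetection is done.
#'
#' @param path Path to the file.
#' @return A [raw_spectrum()].
#' @export
read_spectrum <- function(path) {
  ns_assert(file.exists(path), paste0("no such file: ", path), "parse_error")
  lines <- readLines(path, warn = FALSE)
  meta <- list(subject_id = NA_character_, class_label = NA_character_,
               timestamp_s = NA_real_)
  is_comment <- startsWith(trimws(lines), "#")
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", cl))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  ns_assert(length(data_lines) > 0, paste0("no data lines in ", path), "parse_error")
  wl <- numeric(length(data_lines)); iv <- numeric(length(data_lines))
  for (i in seq_along(data_lines)) {
    fields <- strsplit(trimws(data_lines[i]), "[\t, ]+")[[1]]
    if (length(fields) < 2)
      ns_stop(sprintf("%s: line %d has fewer than 2 columns", path, i), "parse_error")
    v <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(v)))
      ns_stop(sprintf("%s: line %d is not numeric ('%s')", path, i, data_lines[i]),
              "parse_error")
    wl[i] <- v[1]; iv[i] <- v[2]
  }
  if (is.unsorted(wl, strictly = TRUE))
    ns_stop(paste0(path, ": wavelengths are not strictly increasing"), "parse_error")
  raw_spectrum(wl, iv, subject_id = meta$subject_id,
               class_label = meta$class_label,
               timestamp_s = suppressWarnings(as.numeric(meta$timestamp_s)))
}

#' Write a spectrum as two-column delimited text
#'
#' @param x A [raw_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "raw_spectrum"))
  hdr <- c("# needlespec spectrum (wavelength_nm<TAB>intensity_counts)")
  if (!is.na(x$subject_id)) hdr <- c(hdr, paste0("# subject_id: ", x$subject_id))
  if (!is.na(x$class_label)) hdr <- c(hdr, paste0("# class_label: ", x$class_label))
  if (!is.na(x$timestamp_s))
    hdr <- c(hdr, paste0("# timestamp_s: ", format(x$timestamp_s, digits = 17)))
  body <- paste(format(x$wavelengths, digits = 17, trim = TRUE),
                format(x$intensities, digits = 17, trim = TRUE), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a calibration pair as a three-column text file
#'
#' Columns: wavelength, white-standard counts, dark counts.
#' @param x A [calibration_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "calibration_pair"))
  body <- paste(format(x$wavelengths, digits = 17, trim = TRUE),
                format(x$standard, digits = 17, trim = TRUE),
                format(x$noise, digits = 17, trim = TRUE), sep = "\t")
  writeLines(c("# needlespec calibration (wavelength_nm standard dark)", body), path)
  invisible(path)
}

#' Read a calibration pair written by [write_calibration()]
#' @param path Path to the file.
#' @return A [calibration_pair()].
#' @export
read_calibration <- function(path) {
  ns_assert(file.exists(path), paste0("no such file: ", path), "parse_error")
  d <- utils::read.table(path, comment.char = "#")
  ns_assert(ncol(d) >= 3, paste0(path, ": expected 3 columns"), "parse_error")
  calibration_pair(d[[1]], d[[2]], d[[3]])
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `file`, `subject_id`, `class`,
#' `timestamp_s`, one row per recorded spectrum. Class labels outside the
#' eight-class vocabulary are rejected.
#'
#' @param path Path to the CSV.
#' @param check_paths If TRUE, verify each `file` resolves (relative to the
#'   manifest's directory) and error otherwise.
#' @return A `data.frame` of class `dataset_manifest`.
#' @export
read_manifest <- function(path, check_paths = FALSE) {
  ns_assert(file.exists(path), paste0("no such file: ", path), "schema_error")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_manifest(d, dir = dirname(path), check_paths = check_paths)
}

#' Validate a data frame as a dataset manifest
#' @param d Data frame with columns `file`, `subject_id`, `class`, `timestamp_s`.
#' @param dir Base directory against which to resolve relative paths.
#' @param check_paths Verify that files exist.
#' @return `d` with class `dataset_manifest` prepended.
#' @export
as_manifest <- function(d, dir = ".", check_paths = FALSE) {
  need <- c("file", "subject_id", "class", "timestamp_s")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    ns_stop(paste0("manifest lacks column(s): ", paste(missing_cols, collapse = ", ")),
            "schema_error")
  bad <- setdiff(unique(d$class), tissue_classes())
  if (length(bad))
    ns_stop(paste0("unknown class label(s): ", paste(bad, collapse = ", ")),
            "schema_error")
  if (nrow(d) == 0) warning("empty manifest")
  if (check_paths) {
    paths <- ifelse(grepl("^/", d$file), d$file, file.path(dir, d$file))
    gone <- !file.exists(paths)
    if (any(gone))
      ns_stop(paste0("manifest file(s) not found: ",
                     paste(utils::head(d$file[gone], 5), collapse = ", ")),
              "schema_error")
  }
  d$subject_id <- as.character(d$subject_id)
  d$class <- as.character(d$class)
  class(d) <- c("dataset_manifest", "data.frame")
  d
}

#' Write a dataset manifest as CSV
#' @param manifest A manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained classifier
#'
#' Models are stored as a versioned serialized container embedding the
#' feature scheme, classifier configuration, class order and preprocessing
#' provenance, so a loaded model carries everything needed to classify a raw
#' spectrum.
#'
#' @param model A `tissue_classifier` (or `tissue_ensemble`).
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("tissue_classifier", "tissue_ensemble")))
  saveRDS(list(format = "needlespec_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ns_assert(file.exists(path), paste0("no such file: ", path), "parse_error")
  obj <- tryCatch(readRDS(path), error = function(e)
    ns_stop(paste0(path, " is not a needlespec model file"), "parse_error"))
  ns_assert(identical(obj$format, "needlespec_model"),
            paste0(path, " is not a needlespec model file"), "parse_error")
  obj$model
}

#' Write a performance report as CSV and/or JSON
#'
#' The CSV mirrors the per-class statistics table (values rounded half away
#' from zero to 3 decimals, as customarily printed); the JSON keeps full
#' precision and embeds the confusion matrix.
#'
#' @param metrics A `class_metrics` object from [per_class_metrics()].
#' @param cm The `confusion_matrix` it was computed from (JSON only).
#' @param csv,json Output paths (either may be NULL to skip).
#' @return Invisibly, a list of written paths.
#' @export
write_metrics_report <- function(metrics, cm = NULL, csv = NULL, json = NULL) {
  stopifnot(inherits(metrics, "class_metrics"))
  written <- list()
  if (!is.null(csv)) {
    tab <- as.data.frame(metrics)
    tab[-1] <- lapply(tab[-1], round_half_up, digits = 3)
    utils::write.csv(tab, csv, row.names = FALSE)
    written$csv <- csv
  }
  if (!is.null(json)) {
    payload <- list(per_class = as.data.frame(metrics),
                    macro = as.list(metrics$macro),
                    accuracy = metrics$accuracy)
    if (!is.null(cm)) payload$confusion <- list(class_order = colnames(cm),
                                                counts = unclass(cm))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
    written$json <- json
  }
  invisible(written)
}

#' Read back a JSON metrics report
#' @param path Path written by [write_metrics_report()].
#' @return A list with `per_class`, `macro`, `accuracy` (and `confusion` if saved).
#' @export
read_metrics_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
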