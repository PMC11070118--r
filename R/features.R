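# The 25 point-feature wavelengths and 24 slope segments are fixed design
# tables chosen near rising/falling edges, local maxima and minima of the
# eight class mean spectra; they are part of the method definition.

#' Point-feature wavelengths
#'
#' The 25 wavelengths (nm) at which the point scheme reads the processed
#' spectrum, in order.
#' @return Numeric vector of length 25.
#' @export
point_wavelengths <- function() {
  c(485, 500, 515, 545, 553, 563, 570, 580, 590, 600, 610, 625, 640,
    660, 695, 730, 760, 765, 800, 815, 850, 900, 915, 950, 990)
}

#' Slope-feature segments
#'
#' The 24 `(start, end)` wavelength pairs (nm) between which the slope
#' scheme computes finite-difference gradients, in order.
#' @return A 24 x 2 numeric matrix with columns `start` and `end`.
#' @export
slope_segments <- function() {
  starts <- c(450, 475, 485, 500, 515, 530, 550, 565, 580, 590, 600, 620,
              635, 650, 670, 700, 730, 760, 785, 800, 880, 900, 940, 970)
  ends <- c(475, 485, 500, 515, 530, 550, 565, 580, 590, 600, 620, 635,
            650, 670, 700, 730, 760, 785, 800, 880, 900, 940, 970, 1000)
  cbind(start = starts, end = ends)
}

#' Feature-extraction scheme
#'
#' One of the four representations fed to the classifiers:
#' \describe{
#'   \item{full}{every `decimation`-th value of the processed spectrum,
#'     starting at the first point;}
#'   \item{band}{values inside selected wavelength bands, concatenated in
#'     listed order (default 470--520 and 550--890 nm, the visually most
#'     class-discriminative regions);}
#'   \item{point}{the 25 values at [point_wavelengths()];}
#'   \item{slope}{the 24 finite-difference gradients over
#'     [slope_segments()], unitless per nm, which are invariant to additive
#'     intensity offsets.}
#' }
#'
#' @param name One of `"full"`, `"band"`, `"point"`, `"slope"`.
#' @param bands List of length-2 numeric `(low, high)` nm pairs (band
#'   scheme). Overlapping bands duplicate the shared values.
#' @param points Numeric wavelengths, nm (point scheme).
#' @param segments Two-column `(start, end)` matrix, nm (slope scheme).
#' @param decimation Integer >= 1 keep-every-nth factor (full scheme).
#' @param angle_degrees For the slope scheme, report `atan(slope)` in
#'   degrees instead of the raw gradient (default FALSE).
#' @return An object of class `feature_scheme`.
#' @export
#' @examples
#' feature_scheme("full", decimation = 2)
#' feature_scheme("point")
feature_scheme <- function(name = c("full", "band", "point", "slope"),
                           bands = list(c(470, 520), c(550, 890)),
                           points = point_wavelengths(),
                           segments = slope_segments(),
                           decimation = 1L,
                           angle_degrees = FALSE) {
  name <- match.arg(name)
  ns_assert(decimation >= 1, "decimation must be >= 1", "argument_error")
  if (name == "band") {
    ns_assert(length(bands) > 0, "band scheme needs at least one band", "argument_error")
    for (b in bands)
      ns_assert(length(b) == 2 && b[1] < b[2],
                "each band must be (low, high) with low < high", "argument_error")
  }
  if (name == "slope")
    ns_assert(all(segments[, 1] < segments[, 2]),
              "slope segments need start < end", "argument_error")
  structure(list(name = name, bands = bands, points = as.numeric(points),
                 segments = segments, decimation = as.integer(decimation),
                 angle_degrees = isTRUE(angle_degrees)),
            class = "feature_scheme")
}

#' @export
print.feature_scheme <- function(x, ...) {
  detail <- switch(x$name,
    full = sprintf("decimation %d", x$decimation),
    band = paste(vapply(x$bands, function(b) sprintf("%g-%g nm", b[1], b[2]),
                        character(1)), collapse = ", "),
    point = sprintf("%d wavelengths", length(x$points)),
    slope = sprintf("%d segments%s", nrow(x$segments),
                    if (x$angle_degrees) " (degrees)" else ""))
  cat(sprintf("Feature scheme '%s' (%s)\n", x$name, detail))
  invisible(x)
}

extract_full <- function(s, decimation = 1L) {
  ns_assert(decimation >= 1, "decimation must be >= 1", "argument_error")
  s$values[seq(1L, length(s$values), by = as.integer(decimation))]
}

extract_band <- function(s, bands) {
  out <- lapply(bands, function(b) restrict_band(s$wavelengths, s$values, b)$values)
  unlist(out, use.names = FALSE)
}

extract_points <- function(s, points = point_wavelengths()) {
  s$values[wavelength_index(s$wavelengths, points)]
}

extract_slopes <- function(s, segments = slope_segments(), angle_degrees = FALSE) {
  i0 <- wavelength_index(s$wavelengths, segments[, 1])
  i1 <- wavelength_index(s$wavelengths, segments[, 2])
  # gradient per nm over the nominal segment length
  sl <- (s$values[i1] - s$values[i0]) / (segments[, 2] - segments[, 1])
  if (angle_degrees) atan(sl) * 180 / pi else sl
}

#' Extract a feature vector from one processed spectrum
#'
#' @param s A `processed_spectrum`.
#' @param scheme A [feature_scheme()].
#' @return Numeric feature vector (length 25 for point, 24 for slope,
#'   grid-dependent for full/band).
#' @export
extract_features <- function(s, scheme) {
  stopifnot(inherits(scheme, "feature_scheme"))
  v <- switch(scheme$name,
    full = extract_full(s, scheme$decimation),
    band = extract_band(s, scheme$bands),
    point = extract_points(s, scheme$points),
    slope = extract_slopes(s, scheme$segments, scheme$angle_degrees))
  if (!all(is.finite(v)))
    ns_stop("non-finite feature values", "range_error")
  v
}

#' Build a feature matrix for a list of processed spectra
#'
#' @param spectra List of `processed_spectrum` objects on a common grid.
#' @param scheme A [feature_scheme()].
#' @return Numeric matrix, one row per spectrum.
#' @export
featurize <- function(spectra, scheme) {
  rows <- lapply(spectra, extract_features, scheme = scheme)
  n <- lengths(rows)
  ns_assert(length(unique(n)) == 1,
            "spectra yield feature vectors of different lengths", "argument_error")
  do.call(rbind, rows)
}
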