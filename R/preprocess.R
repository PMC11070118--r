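#' Preprocessing configuration
#'
#' Parameters of the raw-to-processed chain. Defaults follow the
#' acquisition protocol the pipeline was designed around: a width-10 moving
#' average (enough to suppress shot-noise ripple while keeping the
#' hemoglobin/water features), per-spectrum min-max normalization, and
#' restriction to 450--1000 nm where the halogen source emits usefully and
#' the detector is sensitive.
#'
#' @param window Moving-average width in samples (>= 1).
#' @param band Length-2 numeric `(low, high)` nm kept after restriction.
#' @param normalize Apply per-spectrum min-max normalization (default TRUE).
#' @param log_absorbance Convert the calibrated ratio to -log10 absorbance
#'   before smoothing (default FALSE: values stay relative intensity).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(window = 10L, band = c(450, 1000),
                              normalize = TRUE, log_absorbance = FALSE) {
  ns_assert(length(window) == 1 && window >= 1, "window must be >= 1", "argument_error")
  ns_assert(length(band) == 2 && band[1] < band[2],
            "band must be (low, high) with low < high", "argument_error")
  structure(list(window = as.integer(window), band = as.numeric(band),
                 normalize = isTRUE(normalize),
                 log_absorbance = isTRUE(log_absorbance)),
            class = "preprocess_config")
}

#' White-standard / dark calibration
#'
#' Converts raw detector counts to relative intensity:
#' `(I_raw - I_noise) / (I_standard - I_noise)` elementwise, which removes
#' both the instrument background and the source/detector spectral response.
#'
#' @param raw A [raw_spectrum()].
#' @param cal A [calibration_pair()] on the same grid.
#' @return Numeric vector of relative intensities (unitless).
#' @export
calibrate <- function(raw, cal) {
  stopifnot(inherits(raw, "raw_spectrum"), inherits(cal, "calibration_pair"))
  ns_assert(length(raw$wavelengths) == length(cal$wavelengths) &&
              max(abs(raw$wavelengths - cal$wavelengths)) < 1e-6,
            "spectrum and calibration pair are on different grids", "calibration_error")
  denom <- cal$standard - cal$noise
  zero <- denom == 0
  if (any(zero))
    ns_stop(paste0("standard - noise is zero at wavelength(s): ",
                   paste(utils::head(format(cal$wavelengths[zero]), 5), collapse = ", ")),
            "calibration_error")
  (raw$intensities - cal$noise) / denom
}

#' Centered moving-average smoothing
#'
#' Output has the same length as the input; near the edges the window is
#' truncated to the available samples. For even windows the extra sample is
#' taken on the right.
#'
#' @param values Numeric vector.
#' @param window Width in samples, 1 <= window <= length(values).
#' @return Smoothed numeric vector.
#' @export
smooth_ma <- function(values, window) {
  n <- length(values)
  window <- as.integer(window)
  ns_assert(length(window) == 1 && window >= 1, "window must be >= 1", "argument_error")
  ns_assert(window <= n, "window exceeds spectrum length", "argument_error")
  if (window == 1L) return(as.numeric(values))
  left <- (window - 1L) %/% 2L
  right <- window %/% 2L
  cs <- c(0, cumsum(as.numeric(values)))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-spectrum min-max normalization
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 1. A
#' constant vector has no dynamic range to rescale (dead detector or
#' saturated spectrum) and raises a normalization error.
#'
#' @param values Numeric vector, non-constant.
#' @return Rescaled vector attaining 0 and 1.
#' @export
minmax_normalize <- function(values) {
  r <- range(values)
  if (!all(is.finite(r)))
    ns_stop("non-finite values in spectrum", "normalization_error")
  if (r[1] == r[2])
    ns_stop("constant spectrum: min equals max (dead detector or saturation?)",
            "normalization_error")
  (values - r[1]) / (r[2] - r[1])
}

#' Restrict a spectrum to a wavelength band
#'
#' Keeps grid points with `low <= lambda <= high` (closed interval); grid
#' and values are cut consistently.
#'
#' @param wavelengths Numeric grid, nm.
#' @param values Values on that grid.
#' @param band Length-2 `(low, high)` nm.
#' @return List with the restricted `wavelengths` and `values`.
#' @export
restrict_band <- function(wavelengths, values, band) {
  ns_assert(length(band) == 2 && band[1] < band[2],
            "band must be (low, high) with low < high", "argument_error")
  keep <- wavelengths >= band[1] & wavelengths <= band[2]
  if (!any(keep))
    ns_stop(sprintf("band [%g, %g] nm contains no grid points", band[1], band[2]),
            "argument_error")
  list(wavelengths = wavelengths[keep], values = values[keep])
}

#' Full preprocessing chain
#'
#' Composition, in order: calibration against the white standard and dark
#' spectrum, moving-average smoothing, min-max normalization (computed over
#' the full pre-restriction spectrum), and band restriction. The returned
#' object records exactly what was applied.
#'
#' @param raw A [raw_spectrum()].
#' @param cal A [calibration_pair()].
#' @param config A [preprocess_config()].
#' @return An object of class `processed_spectrum` with fields
#'   `wavelengths`, `values` (unitless, in `[0, 1]` when normalized) and
#'   `provenance` (window, band, flags, input/output lengths), carrying the
#'   raw spectrum's metadata.
#' @export
#' @examples
#' g <- canonical_grid()
#' cal <- calibration_pair(g, rep(40000, length(g)), rep(1800, length(g)))
#' raw <- raw_spectrum(g, 1800 + 38200 * seq(0.2, 0.8, length.out = length(g)))
#' p <- preprocess(raw, cal, preprocess_config())
#' range(p$values)
preprocess <- function(raw, cal, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  v <- calibrate(raw, cal)
  if (config$log_absorbance) v <- -log10(pmax(v, 1e-9))
  v <- smooth_ma(v, config$window)
  if (config$normalize) v <- minmax_normalize(v)
  cut <- restrict_band(raw$wavelengths, v, config$band)
  structure(list(
    wavelengths = cut$wavelengths,
    values = cut$values,
    provenance = list(window = config$window, band = config$band,
                      normalize = config$normalize,
                      log_absorbance = config$log_absorbance,
                      n_in = length(raw$wavelengths),
                      n_out = length(cut$values)),
    subject_id = raw$subject_id, class_label = raw$class_label,
    timestamp_s = raw$timestamp_s),
    class = "processed_spectrum")
}

#' @export
print.processed_spectrum <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "Processed spectrum: %d points, %.1f-%.1f nm (window %d, band %g-%g nm, %s)\n",
    length(x$values), min(x$wavelengths), max(x$wavelengths),
    p$window, p$band[1], p$band[2],
    if (p$normalize) "min-max normalized" else "unnormalized"))
  invisible(x)
}

#' @export
plot.processed_spectrum <- function(x, ...) {
  graphics::plot(x$wavelengths, x$values, type = "l",
                 xlab = "wavelength (nm)", ylab = "relative intensity",
                 main = if (!is.na(x$class_label)) x$class_label else "", ...)
  invisible(x)
}
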