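#' Preprocess every spectrum of a dataset
#'
#' @param spectra List of [raw_spectrum()]s.
#' @param cal A [calibration_pair()].
#' @param config A [preprocess_config()].
#' @return List of `processed_spectrum` objects.
#' @export
preprocess_all <- function(spectra, cal, config = preprocess_config()) {
  lapply(spectra, preprocess, cal = cal, config = config)
}

#' Feature matrices for all four schemes
#'
#' Convenience wrapper producing the named list of feature matrices that
#' [cross_validate()] consumes.
#'
#' @param processed List of `processed_spectrum` objects.
#' @param decimation Decimation for the full scheme (default 2).
#' @return Named list of matrices: `full`, `band`, `point`, `slope`.
#' @export
feature_matrices <- function(processed, decimation = 2L) {
  list(full = featurize(processed, feature_scheme("full", decimation = decimation)),
       band = featurize(processed, feature_scheme("band")),
       point = featurize(processed, feature_scheme("point")),
       slope = featurize(processed, feature_scheme("slope")))
}
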