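#' Reference real-time validation confusion matrix
#'
#' The bundled confusion matrix of a two-subject ex vivo real-time
#' validation session with the optical needle probe: 286 spectra across the
#' eight classes (19 ambient, 39 blood, 38 of each tissue), classified at
#' 2 Hz by the final full-range SVM model. Rows are true classes, columns
#' predictions. All 19 ambient samples were recognized correctly; the three
#' ambient false positives (one fat, two heart) are taken from the per-row
#' entries, which are authoritative over the session's summary column
#' totals. Useful as a worked input for [per_class_metrics()].
#'
#' @return A `confusion_matrix` with total 286.
#' @export
#' @examples
#' cm <- reference_confusion()
#' sum(cm)
#' per_class_metrics(cm)
reference_confusion <- function() {
  path <- system.file("extdata", "realtime_confusion.csv", package = "needlespec",
                      mustWork = TRUE)
  d <- utils::read.csv(path, row.names = 1)
  as_confusion_matrix(as.matrix(d), class_order = rownames(d))
}
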