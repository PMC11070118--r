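# Simulated continuous classification: a fixed-rate stream of spectra is
# classified one by one through the same preprocess -> featurize -> predict
# chain as batch training, with samples at class-period boundaries excluded
# from the summary (tissue changes are never perfectly synchronized with
# the recording clock).

#' Assemble a fixed-rate streaming session
#'
#' Orders spectra into contiguous class periods according to `schedule`
#' (the measurement order; the original protocol measured fat, muscle,
#' lung, kidney, liver, heart, then blood, with blood last due to
#' ruddiness) and stamps them at a fixed sampling period.
#'
#' @param spectra List of [raw_spectrum()]s with `class_label` set.
#' @param schedule Character vector of class labels in measurement order,
#'   or a data frame with columns `class` and `n` (samples per period).
#'   With a character vector, all available spectra of each class are used.
#' @param period Sampling period in seconds (default 0.5, i.e. 2 Hz).
#' @param boundary_exclusion Samples flagged as excluded on each side of
#'   every internal class-period boundary (default 1).
#' @return An object of class `stream_session`.
#' @export
make_session <- function(spectra, schedule, period = 0.5, boundary_exclusion = 1L) {
  ns_assert(length(schedule) > 0, "empty schedule", "argument_error")
  ns_assert(period > 0, "period must be positive", "argument_error")
  ns_assert(boundary_exclusion >= 0, "boundary_exclusion must be >= 0", "argument_error")
  if (!is.data.frame(schedule))
    schedule <- data.frame(class = as.character(schedule), n = NA_integer_,
                           stringsAsFactors = FALSE)
  ns_assert(nrow(schedule) > 0, "empty schedule", "argument_error")
  have <- vapply(spectra, function(s) s$class_label, character(1))
  ordered <- list(); labels <- character(0)
  periods <- data.frame(class = character(0), start = integer(0), end = integer(0))
  for (i in seq_len(nrow(schedule))) {
    cl <- schedule$class[i]
    avail <- which(have == cl)
    if (length(avail) == 0)
      ns_stop(paste0("no spectra available for scheduled class: ", cl),
              "argument_error")
    n <- schedule$n[i]
    if (is.na(n)) n <- length(avail)
    ns_assert(length(avail) >= n,
              paste0("fewer spectra than scheduled for class ", cl), "argument_error")
    take <- avail[seq_len(n)]
    start <- length(labels) + 1L
    ordered <- c(ordered, spectra[take])
    labels <- c(labels, rep(cl, n))
    periods <- rbind(periods, data.frame(class = cl, start = start,
                                         end = length(labels)))
  }
  structure(list(spectra = ordered, labels = labels,
                 timestamps = (seq_along(labels) - 1) * period,
                 period = period, periods = periods,
                 boundary_exclusion = as.integer(boundary_exclusion)),
            class = "stream_session")
}

#' @export
print.stream_session <- function(x, ...) {
  cat(sprintf("Streaming session: %d samples at %.2g Hz (%d class periods, exclude %d/boundary side)\n",
              length(x$labels), 1 / x$period, nrow(x$periods), x$boundary_exclusion))
  cat("  order:", paste(x$periods$class, collapse = " -> "), "\n")
  invisible(x)
}

# Indices flagged as excluded: boundary_exclusion samples on each side of
# every internal period boundary. Never touches non-boundary samples.
boundary_excluded <- function(session) {
  b <- session$boundary_exclusion
  if (b == 0 || nrow(session$periods) < 2) return(integer(0))
  out <- integer(0)
  for (i in seq_len(nrow(session$periods) - 1)) {
    e <- session$periods$end[i]          # last index of period i
    left <- seq.int(max(session$periods$start[i], e - b + 1L), e)
    s <- session$periods$start[i + 1]    # first index of period i+1
    right <- seq.int(s, min(session$periods$end[i + 1], s + b - 1L))
    out <- c(out, left, right)
  }
  sort(unique(out))
}

#' Run a model over a streaming session
#'
#' Processes each spectrum independently in arrival order: calibration,
#' smoothing, normalization, band restriction (per the model's recorded
#' preprocessing configuration), feature extraction with the model's
#' scheme, and prediction. Boundary samples are classified but excluded
#' from the summary statistics. A preprocessing failure on one sample flags
#' that sample and the stream continues. Per-sample latency is recorded for
#' information only.
#'
#' @param session A [make_session()] session.
#' @param model A `tissue_classifier` with its `scheme` set.
#' @param cal The session's [calibration_pair()].
#' @param config [preprocess_config()] used for every sample (defaults to
#'   the model's recorded configuration, else the package default).
#' @param realtime If TRUE, sleep to honor the session's wall-clock pacing
#'   (demo use only).
#' @return An object of class `stream_result`: `samples` data frame
#'   (timestamp, true class, predicted class, top score, excluded/error
#'   flags, processing seconds), `scores` matrix, `confusion` and `metrics`
#'   over the non-excluded samples, and `n_errors`.
#' @export
stream_classify <- function(session, model, cal, config = NULL, realtime = FALSE) {
  stopifnot(inherits(session, "stream_session"),
            inherits(model, "tissue_classifier"))
  ns_assert(!is.null(model$scheme),
            "model has no recorded feature scheme", "inference_error")
  if (is.null(config)) config <- model$preprocess
  if (is.null(config)) config <- preprocess_config()
  n <- length(session$spectra)
  excluded <- seq_len(n) %in% boundary_excluded(session)
  pred <- rep(NA_character_, n)
  top <- rep(NA_real_, n)
  err <- logical(n)
  lat <- numeric(n)
  scores <- matrix(NA_real_, n, length(model$class_order),
                   dimnames = list(NULL, model$class_order))
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      p <- preprocess(session$spectra[[i]], cal, config)
      f <- matrix(extract_features(p, model$scheme), nrow = 1)
      s <- predict_scores(model, f)
      list(label = predict(model, f), s = s)
    }, needlespec_error = function(e) e)
    if (inherits(res, "error")) {
      err[i] <- TRUE
    } else {
      pred[i] <- res$label
      scores[i, ] <- res$s
      top[i] <- max(res$s)
    }
    lat[i] <- proc.time()[["elapsed"]] - t0
    if (realtime && lat[i] < session$period)
      Sys.sleep(session$period - lat[i])
  }
  use <- !excluded & !err
  cm <- confusion_matrix(session$labels[use], pred[use],
                         class_order = model$class_order)
  structure(list(
    samples = data.frame(timestamp_s = session$timestamps,
                         true = session$labels, predicted = pred,
                         top_score = top, excluded = excluded, error = err,
                         latency_s = lat, stringsAsFactors = FALSE),
    scores = scores,
    confusion = cm,
    metrics = per_class_metrics(cm),
    n_errors = sum(err)), class = "stream_result")
}

#' @export
print.stream_result <- function(x, ...) {
  n <- nrow(x$samples)
  nex <- sum(x$samples$excluded)
  cat(sprintf("Stream result: %d samples (%d excluded at boundaries, %d errors)\n",
              n, nex, x$n_errors))
  cat(sprintf("  accuracy on analyzed samples: %.3f\n", x$metrics$accuracy))
  cat(sprintf("  mean latency: %.4f s\n", mean(x$samples$latency_s)))
  invisible(x)
}
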