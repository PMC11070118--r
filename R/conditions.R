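# Classed error conditions so callers and tests can discriminate failure modes.

ns_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "needlespec_error", "error", "condition"),
                      call = call))
}

ns_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) ns_stop(msg, class, call = sys.call(-1))
  invisible(TRUE)
}

#' The eight-class label vocabulary
#'
#' Class labels used throughout the pipeline: laboratory ambient light plus
#' the seven rat tissue types, in alphabetical order. This order is the
#' default `class_order` everywhere a label ordering is needed.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  c("ambient", "blood", "fat", "heart", "kidney", "liver", "lung", "muscle")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (reports print like published tables; R's
# round() would do banker's rounding at .5 ties).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
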