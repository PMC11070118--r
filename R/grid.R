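#' Canonical spectrometer wavelength grid
#'
#' The acquisition grid assumed throughout: 1044 points linearly spaced over
#' 348--1129 nm, matching a broadband VIS/NIR spectrometer readout. (The
#' nominal 0.7 nm optical resolution and the 1044-point count are mutually
#' inconsistent; the point count is authoritative because every downstream
#' vector length depends on it.)
#'
#' @return Numeric vector of 1044 strictly increasing wavelengths in nm.
#' @export
#' @examples
#' g <- canonical_grid()
#' length(g)
#' range(g)
canonical_grid <- function() {
  seq(348, 1129, length.out = 1044L)
}

#' Nearest grid index for a wavelength
#'
#' Maps target wavelengths to indices of the nearest grid points. Exact
#' midpoints between two grid points resolve to the lower index. Targets
#' falling outside the grid span by more than one grid step raise a range
#' error.
#'
#' @param grid Strictly increasing numeric wavelength grid (nm).
#' @param lambda Numeric vector of target wavelengths (nm).
#' @return Integer vector of indices into `grid`, same length as `lambda`.
#' @export
#' @examples
#' wavelength_index(c(500, 501, 502), 501.4)
wavelength_index <- function(grid, lambda) {
  ns_assert(length(grid) > 0 && !is.unsorted(grid, strictly = TRUE),
            "grid must be nonempty and strictly increasing", "argument_error")
  step <- if (length(grid) > 1) max(diff(grid)) else Inf
  out <- integer(length(lambda))
  for (i in seq_along(lambda)) {
    l <- lambda[i]
    if (l < grid[1] - step || l > grid[length(grid)] + step)
      ns_stop(sprintf("wavelength %.6g nm lies outside the grid span [%.6g, %.6g]",
                      l, grid[1], grid[length(grid)]), "range_error")
    j <- findInterval(l, grid, all.inside = TRUE)
    # candidate j or j+1; ties (equal distance) break toward the lower index
    if (j < length(grid) && (grid[j + 1] - l) < (l - grid[j])) j <- j + 1L
    out[i] <- j
  }
  out
}
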