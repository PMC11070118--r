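# Synthetic spectra generator. Emulates the statistical structure of
# needle-probe recordings: eight classes with distinct smooth spectral
# shapes, per-subject smooth gain perturbations (inter-animal variation),
# per-spectrum overall intensity variation, and additive high-frequency
# detector noise, all on the canonical 1044-point grid with one shared
# white-standard/dark calibration pair.

#' Synthetic dataset configuration
#'
#' @param n_subjects Number of subjects (animals), >= 1.
#' @param spectra_per_class_per_subject Replicates per class per subject, >= 1.
#' @param subject_effect_scale SD of the per-subject smooth log-gain
#'   perturbation (unitless). 0 disables subject effects.
#' @param intensity_range `(min, max)` of the per-spectrum overall scale
#'   factor (uniform); mimics the strongly varying recorded intensities.
#' @param noise_sd SD of additive i.i.d. Gaussian noise on the calibrated
#'   (relative-intensity) scale.
#' @param class_separation Multiplier >= 0 on between-class shape
#'   differences: 0 collapses all classes onto the mean shape, 1 keeps the
#'   archetypes as designed.
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   bitwise.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 8L,
                             spectra_per_class_per_subject = 20L,
                             subject_effect_scale = 0.08,
                             intensity_range = c(0.5, 2),
                             noise_sd = 0.02,
                             class_separation = 1,
                             seed = 1L) {
  ns_assert(n_subjects >= 1, "n_subjects must be >= 1", "config_error")
  ns_assert(spectra_per_class_per_subject >= 1,
            "spectra_per_class_per_subject must be >= 1", "config_error")
  ns_assert(subject_effect_scale >= 0, "subject_effect_scale must be >= 0", "config_error")
  ns_assert(length(intensity_range) == 2 && intensity_range[1] < intensity_range[2] &&
              intensity_range[1] > 0,
            "intensity_range must be (min, max) with 0 < min < max", "config_error")
  ns_assert(noise_sd >= 0, "noise_sd must be >= 0", "config_error")
  ns_assert(class_separation >= 0, "class_separation must be >= 0", "config_error")
  structure(list(n_subjects = as.integer(n_subjects),
                 spectra_per_class_per_subject = as.integer(spectra_per_class_per_subject),
                 subject_effect_scale = subject_effect_scale,
                 intensity_range = as.numeric(intensity_range),
                 noise_sd = noise_sd,
                 class_separation = class_separation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Class archetypes: smooth reference reflectance shapes
#'
#' Each archetype is a sum of Gaussian bumps/dips, a logistic step and a
#' linear baseline, parameterized in a bundled table
#' (`inst/extdata/archetypes.csv`). All eight share the qualitative anatomy
#' of diffuse tissue reflectance in the VIS/NIR: a wide peak around
#' 470--520 nm, a step rise near 600 nm (hemoglobin absorption falling
#' off), a negative deoxyhemoglobin peak at 760 nm, and for blood
#' additional peaks above 900 nm. Fat and muscle are deliberately the most
#' similar pair. Amplitudes are qualitative stand-ins, not calibrated to
#' any measured tissue.
#'
#' @return A list of 8 objects of class `class_archetype`, named by class.
#' @export
#' @examples
#' a <- default_archetypes()
#' names(a)
default_archetypes <- function() {
  path <- system.file("extdata", "archetypes.csv", package = "needlespec",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  grid_range <- range(canonical_grid())
  out <- lapply(tissue_classes(), function(cl) {
    rows <- d[d$class == cl, , drop = FALSE]
    ns_assert(nrow(rows) > 0, paste0("no archetype rows for class ", cl), "config_error")
    centers <- rows$center_nm[!is.na(rows$center_nm)]
    widths <- rows$width_nm[!is.na(rows$width_nm)]
    ns_assert(all(centers >= grid_range[1] & centers <= grid_range[2]),
              paste0(cl, ": component center outside the grid"), "config_error")
    ns_assert(all(widths > 0), paste0(cl, ": nonpositive component width"), "config_error")
    structure(list(class_label = cl, components = rows), class = "class_archetype")
  })
  names(out) <- tissue_classes()
  out
}

#' Evaluate an archetype curve on a wavelength grid
#'
#' @param archetype A `class_archetype`.
#' @param grid Numeric wavelengths, nm (default [canonical_grid()]).
#' @return Numeric vector of unitless reference reflectance values.
#' @export
archetype_curve <- function(archetype, grid = canonical_grid()) {
  stopifnot(inherits(archetype, "class_archetype"))
  v <- numeric(length(grid))
  for (i in seq_len(nrow(archetype$components))) {
    r <- archetype$components[i, ]
    v <- v + switch(r$type,
      baseline = rep(r$amplitude, length(grid)),
      gauss = r$amplitude * exp(-0.5 * ((grid - r$center_nm) / r$width_nm)^2),
      step = r$amplitude / (1 + exp(-(grid - r$center_nm) / r$width_nm)),
      slope = r$amplitude * (grid - grid[1]),
      ns_stop(paste0("unknown component type: ", r$type), "config_error"))
  }
  ns_assert(all(is.finite(v)), "archetype curve is not finite everywhere", "config_error")
  v
}

# Per-subject smooth multiplicative gain: exp of a random degree-2
# Chebyshev polynomial over the grid. A smooth (not white) perturbation is
# what survives min-max normalization and therefore what actually drives
# the pooled-CV vs subject-holdout accuracy gap.
subject_gain <- function(grid, scale) {
  t <- 2 * (grid - min(grid)) / diff(range(grid)) - 1
  a <- stats::rnorm(3, 0, scale)
  exp(a[1] + a[2] * t + a[3] * (2 * t^2 - 1))
}

#' Generate a labeled multi-subject synthetic dataset
#'
#' Produces `n_subjects x 8 classes x spectra_per_class_per_subject` raw
#' spectra on the canonical grid, a shared calibration pair (flat white
#' standard, small constant dark), and a manifest. Counts are built as
#' `dark + (standard - dark) * scale * gain_subject(lambda) * R_class(lambda)`
#' plus additive noise, so calibration recovers
#' `scale * gain * reflectance + noise` exactly. Class shapes are
#' `mean + class_separation * (archetype - mean)`, floored well above zero.
#'
#' @param config A [synthetic_config()].
#' @param archetypes List of 8 `class_archetype`s (default
#'   [default_archetypes()]).
#' @param dir Optional directory: when given, spectra, the calibration pair
#'   and the manifest are also written there as text files and the manifest
#'   `file` column points at them.
#' @return A list of class `synthetic_dataset` with elements `spectra`
#'   (list of [raw_spectrum()]), `calibration` (a [calibration_pair()]),
#'   `manifest` (a `dataset_manifest`) and `config`.
#' @export
#' @examples
#' d <- generate_dataset(synthetic_config(n_subjects = 2,
#'   spectra_per_class_per_subject = 1, seed = 7))
#' nrow(d$manifest)
generate_dataset <- function(config, archetypes = default_archetypes(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ns_assert(length(archetypes) == 8, "need 8 class archetypes", "config_error")
  grid <- canonical_grid()
  dark <- rep(1800, length(grid))
  standard <- rep(40000, length(grid))
  span <- standard - dark

  curves <- vapply(archetypes, archetype_curve, numeric(length(grid)), grid = grid)
  m <- rowMeans(curves)
  curves <- m + config$class_separation * (curves - m)
  curves <- pmax(curves, 0.02)  # keep reflectance strictly positive

  classes <- tissue_classes()
  spectra <- vector("list", config$n_subjects * 8L * config$spectra_per_class_per_subject)
  rec <- vector("list", length(spectra))
  idx <- 0L
  with_seed(config$seed, {
    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("subject%02d", s)
      gain <- if (config$subject_effect_scale > 0)
        subject_gain(grid, config$subject_effect_scale) else rep(1, length(grid))
      for (cl in classes) {
        for (r in seq_len(config$spectra_per_class_per_subject)) {
          idx <- idx + 1L
          scale <- stats::runif(1, config$intensity_range[1], config$intensity_range[2])
          clean <- dark + span * scale * gain * curves[, cl]
          eps <- if (config$noise_sd > 0)
            stats::rnorm(length(grid), 0, config$noise_sd) else 0
          counts <- clean + span * eps
          ts <- (idx - 1L) * 0.5
          spectra[[idx]] <- raw_spectrum(grid, counts, subject_id = sid,
                                         class_label = cl, timestamp_s = ts)
          rec[[idx]] <- data.frame(file = sprintf("%s_%s_%03d.txt", sid, cl, r),
                                   subject_id = sid, class = cl, timestamp_s = ts,
                                   stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- as_manifest(do.call(rbind, rec))
  cal <- calibration_pair(grid, standard, dark)
  ds <- structure(list(spectra = spectra, calibration = cal,
                       manifest = manifest, config = config),
                  class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a synthetic dataset to disk
#'
#' Spectra become two-column tab-delimited text files, the calibration pair
#' a three-column file (`calibration.txt`), the manifest `manifest.csv`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$spectra))
    write_spectrum(dataset$spectra[[i]], file.path(dir, dataset$manifest$file[i]))
  write_calibration(dataset$calibration, file.path(dir, "calibration.txt"))
  write_manifest(dataset$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Load a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv`, `calibration.txt` and the
#'   spectrum files.
#' @return A `synthetic_dataset`-shaped list (without `config`).
#' @export
read_dataset <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"), check_paths = TRUE)
  spectra <- lapply(seq_len(nrow(manifest)), function(i) {
    sp <- read_spectrum(file.path(dir, manifest$file[i]))
    sp$subject_id <- manifest$subject_id[i]
    sp$class_label <- manifest$class[i]
    sp$timestamp_s <- manifest$timestamp_s[i]
    sp
  })
  structure(list(spectra = spectra,
                 calibration = read_calibration(file.path(dir, "calibration.txt")),
                 manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic needle-probe dataset: %d spectra, %d subjects, %d classes\n",
              length(x$spectra), length(unique(x$manifest$subject_id)),
              length(unique(x$manifest$class))))
  invisible(x)
}
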