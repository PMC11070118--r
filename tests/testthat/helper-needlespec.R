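# Shared fixtures and independent oracles, all built in code.

# A flat calibration pair on a given grid (standard 1, dark 0 by default).
flat_cal <- function(grid, standard = 1, noise = 0) {
  calibration_pair(grid, rep(standard, length(grid)), rep(noise, length(grid)))
}

# Wrap bare values as a processed spectrum on a given grid (bypasses the
# chain; used to probe feature extractors with analytically known inputs).
fake_processed <- function(wavelengths, values) {
  structure(list(wavelengths = wavelengths, values = values,
                 provenance = list(window = NA, band = range(wavelengths),
                                   normalize = NA, log_absorbance = FALSE,
                                   n_in = length(values), n_out = length(values)),
                 subject_id = NA_character_, class_label = NA_character_,
                 timestamp_s = NA_real_),
            class = "processed_spectrum")
}

# Class counts of the validation arm of the original study design:
# 19 ambient, 39 blood, 38 each other tissue (total 286).
validation_counts <- function() {
  c(ambient = 19L, blood = 39L, fat = 38L, heart = 38L, kidney = 38L,
    liver = 38L, lung = 38L, muscle = 38L)
}

# Class counts of the training/model-selection arm (total 1317).
training_counts <- function() {
  c(ambient = 85L, blood = 152L, fat = 165L, heart = 109L, kidney = 247L,
    liver = 201L, lung = 121L, muscle = 237L)
}

labels_from_counts <- function(counts) rep(names(counts), counts)

# Brute-force KNN oracle: per-query loop, explicit distance formulas,
# majority vote, ties broken by the nearest neighbor among tied classes.
# Independent of the package's vectorized implementation.
knn_oracle <- function(train_x, train_y, query, k, metric = "euclidean") {
  train_y <- as.character(train_y)
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      v <- query[i, ] - train_x[j, ]
      d[j] <- if (metric == "euclidean") sqrt(sum(v^2)) else sum(abs(v))
    }
    ord <- order(d)
    nn <- train_y[ord[seq_len(k)]]
    tab <- table(nn)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) {
      out[i] <- winners
    } else {
      cls_sorted <- train_y[ord]
      out[i] <- cls_sorted[cls_sorted %in% winners][1]
    }
  }
  out
}

# Brute-force one-vs-rest metrics oracle: per-sample counting loops.
metrics_oracle <- function(truth, predicted, classes) {
  n <- length(truth)
  per <- lapply(classes, function(cl) {
    tp <- fn <- fp <- tn <- 0
    for (i in seq_len(n)) {
      t_pos <- truth[i] == cl; p_pos <- predicted[i] == cl
      if (t_pos && p_pos) tp <- tp + 1
      else if (t_pos && !p_pos) fn <- fn + 1
      else if (!t_pos && p_pos) fp <- fp + 1
      else tn <- tn + 1
    }
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (!is.na(sens) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
  })
  do.call(rbind, per)
}

# Small low-noise dataset reused by classification tests.
small_dataset <- function(seed = 101, n_subjects = 4, reps = 3, noise = 0.005) {
  generate_dataset(synthetic_config(n_subjects = n_subjects,
                                    spectra_per_class_per_subject = reps,
                                    noise_sd = noise, seed = seed))
}
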