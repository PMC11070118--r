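test_that("stratified folds on the study-sized manifest give 263-264 validation samples", {
  labels <- labels_from_counts(training_counts())  # 1317 samples
  folds <- stratified_kfold(labels, k = 5, seed = 7)
  sizes <- vapply(folds, function(f) length(f$validation), integer(1))
  expect_true(all(sizes %in% c(263L, 264L)))
  # validation sets partition the data
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_identical(all_val, seq_along(labels))
  # per-class counts differ by at most 1 across folds
  for (cl in unique(labels)) {
    per_fold <- vapply(folds, function(f) sum(labels[f$validation] == cl), integer(1))
    expect_lte(diff(range(per_fold)), 1)
  }
  # train and validation are complementary
  for (f in folds)
    expect_identical(sort(c(f$train, f$validation)), seq_along(labels))
})

test_that("stratified folds handle small balanced classes and reject too-small ones", {
  labels <- rep(c("liver", "lung"), each = 10)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  for (f in folds) {
    expect_equal(sum(labels[f$validation] == "liver"), 2)
    expect_equal(sum(labels[f$validation] == "lung"), 2)
  }
  err <- expect_error(stratified_kfold(c(rep("liver", 10), rep("lung", 3)), k = 5),
                      class = "argument_error")
  expect_match(conditionMessage(err), "lung")
})

test_that("linear SVM separates separable classes and is seed-stable", {
  set.seed(88)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 5), 30))
  y <- rep(c("heart", "kidney"), each = 30)
  fit <- tissue_classifier(x, y, kind = "svm", seed = 1)
  expect_equal(mean(predict(fit, x) == y), 1.0)
  refit <- tissue_classifier(x, y, kind = "svm", seed = 1)
  expect_identical(predict(refit, x), predict(fit, x))

  expect_error(tissue_classifier(x, rep("heart", 60)), class = "training_error")
  x[1, 1] <- NaN
  expect_error(tissue_classifier(x, y), class = "training_error")
})

test_that("KNN agrees exactly with the brute-force distance oracle", {
  set.seed(19)
  for (metric in c("euclidean", "manhattan")) {
    for (rep in 1:3) {
      n <- sample(20:50, 1)
      x <- matrix(rnorm(n * 4), n)
      y <- sample(c("fat", "muscle", "liver"), n, replace = TRUE)
      while (length(unique(y)) < 2) y <- sample(c("fat", "muscle", "liver"), n, replace = TRUE)
      q <- matrix(rnorm(15 * 4), 15)
      fit <- tissue_classifier(x, y, kind = "knn", knn_k = 3, knn_metric = metric)
      expect_identical(predict(fit, q), knn_oracle(x, y, q, 3, metric),
                       info = paste(metric, rep))
    }
  }
  # a query identical to a training point includes itself among neighbors
  x <- matrix(c(0, 0, 0.1, 0, 0.2, 0, 5, 5, 5.1, 5), ncol = 2, byrow = TRUE)
  y <- c("fat", "fat", "fat", "muscle", "muscle")
  fit <- tissue_classifier(x, y, kind = "knn", knn_k = 3)
  expect_identical(predict(fit, x[1, , drop = FALSE]), "fat")
  expect_identical(predict(fit, x), knn_oracle(x, y, x, 3))
})

test_that("mahalanobis KNN runs and matches euclidean on whitened data", {
  set.seed(23)
  x <- matrix(rnorm(40 * 3), 40)   # identity covariance: metrics coincide
  y <- rep(c("liver", "lung"), 20)
  q <- matrix(rnorm(10 * 3), 10)
  fit_m <- tissue_classifier(x, y, kind = "knn", knn_metric = "mahalanobis")
  expect_length(predict(fit_m, q), 10)
  expect_true(all(rowSums(predict_scores(fit_m, q)) - 1 < 1e-12))
})

test_that("score vectors are normalized and consistent with predictions", {
  d <- small_dataset(seed = 41, n_subjects = 2, reps = 2)
  pp <- preprocess_all(d$spectra, d$calibration)
  X <- featurize(pp, feature_scheme("point"))
  y <- d$manifest$class
  for (kind in c("svm", "knn")) {
    fit <- tissue_classifier(X, y, kind = kind)
    S <- predict_scores(fit, X)
    expect_equal(rowSums(S), rep(1, nrow(S)), tolerance = 1e-12)
    expect_true(all(S >= 0))
    pred <- predict(fit, X)
    unique_max <- apply(S, 1, function(r) sum(r == max(r)) == 1)
    expect_identical(pred[unique_max],
                     colnames(S)[apply(S[unique_max, , drop = FALSE], 1, which.max)])
  }
  # KNN: all k neighbors of one class give that class score 1
  fit3 <- tissue_classifier(matrix(c(0, 0.1, 0.2, 9), ncol = 1),
                            c("fat", "fat", "fat", "muscle"), kind = "knn")
  expect_equal(unname(predict_scores(fit3, matrix(0.05, 1, 1))[1, "fat"]), 1)
  expect_error(predict_scores(fit3, matrix(0, 1, 5)), class = "inference_error")
})

test_that("score-averaged combinations behave as specified", {
  d <- small_dataset(seed = 51, n_subjects = 2, reps = 2)
  pp <- preprocess_all(d$spectra, d$calibration)
  Xp <- featurize(pp, feature_scheme("point"))
  Xs <- featurize(pp, feature_scheme("slope"))
  y <- d$manifest$class

  # single-member combination is exactly that model
  for (kind in c("svm", "knn")) {
    fit <- tissue_classifier(Xp, y, kind = kind)
    ens <- combine_models(list(fit))
    expect_identical(predict(ens, list(Xp)), predict(fit, Xp))
  }

  # two members with identical scores keep the same argmax
  fit_a <- tissue_classifier(Xp, y, kind = "svm")
  twin <- combine_models(list(fit_a, fit_a))
  expect_identical(predict(twin, list(Xp, Xp)), predict(fit_a, Xp))

  # averaging actually averages
  fit_b <- tissue_classifier(Xs, y, kind = "svm")
  both <- combine_models(list(fit_a, fit_b))
  S <- predict_scores_ensemble(both, list(Xp, Xs))
  expect_equal(S, (predict_scores(fit_a, Xp) + predict_scores(fit_b, Xs)) / 2)

  # symmetric tie breaks toward the earlier class in class_order
  xa <- matrix(c(0, 10), ncol = 1); xb <- matrix(c(10, 0), ncol = 1)
  yy <- factor(c("fat", "muscle"), levels = c("fat", "muscle"))
  m1 <- tissue_classifier(xa, yy, kind = "knn", knn_k = 1)
  m2 <- tissue_classifier(xb, yy, kind = "knn", knn_k = 1)
  q <- matrix(1, 1, 1)  # m1 votes fat, m2 votes muscle -> 0.5 / 0.5
  expect_equal(unname(predict_scores_ensemble(combine_models(list(m1, m2)),
                                              list(q, q))[1, ]), c(0.5, 0.5))
  expect_identical(predict(combine_models(list(m1, m2)), list(q, q)), "fat")

  # mismatched class orders are rejected
  m3 <- tissue_classifier(rbind(xa, xb), factor(c("liver", "lung", "liver", "lung")),
                          kind = "knn", knn_k = 1)
  expect_error(combine_models(list(m1, m3)), class = "combination_error")
})

test_that("cross-validation reports folds plus an average row and ranks models", {
  d <- small_dataset(seed = 61, n_subjects = 2, reps = 3)
  pp <- preprocess_all(d$spectra, d$calibration)
  fm <- feature_matrices(pp)
  specs <- list(svm_point = list(kind = "svm", scheme_name = "point"),
                knn_slope = list(kind = "knn", scheme_name = "slope"))
  cv <- cross_validate(fm, d$manifest$class, classifiers = specs,
                       combinations = list(both = c("svm_point", "knn_slope")),
                       k = 5, seed = 61)
  expect_equal(nrow(cv), 6)
  expect_identical(cv$fold[6], "Average")
  expect_true(all(unlist(cv[6, -1]) > 0.9))  # well-separated low-noise classes
  expect_setequal(attr(cv, "ranking"), c("svm_point", "knn_slope", "both"))
  expect_equal(unname(unlist(cv[6, -1])), unname(colMeans(as.matrix(cv[1:5, -1]))))
})

test_that("subject holdout never mixes subjects across the split", {
  d <- small_dataset(seed = 71, n_subjects = 4, reps = 2)
  sp <- subject_holdout_split(d$manifest, c("subject03", "subject04"))
  expect_length(intersect(d$manifest$subject_id[sp$train],
                          d$manifest$subject_id[sp$test]), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_len(nrow(d$manifest)))

  expect_error(subject_holdout_split(d$manifest, "subject99"), class = "argument_error")
  expect_error(subject_holdout_split(d$manifest, sprintf("subject%02d", 1:4)),
               class = "argument_error")

  # validation-arm-sized holdout: two held-out subjects carrying 286 spectra
  counts <- validation_counts()
  man <- as_manifest(data.frame(
    file = sprintf("f%04d.txt", 1:(sum(counts) + 40)),
    subject_id = c(rep("subject07", 150), rep("subject08", 136), rep("subject01", 40)),
    class = c(labels_from_counts(counts), rep("liver", 40)),
    timestamp_s = 0))
  sp2 <- subject_holdout_split(man, c("subject07", "subject08"))
  expect_length(sp2$test, 286)
})
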