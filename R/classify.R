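#' Fit a tissue classifier
#'
#' The central fitting function: trains a multiclass SVM (one-vs-rest
#' binary margins, via libsvm) or a k-nearest-neighbors model on a feature
#' matrix. Together with the four feature schemes this yields the eight
#' canonical classifiers (SVM/KNN x full/band/point/slope).
#'
#' SVM defaults to a linear kernel with cost 1 (the linear kernel
#' outperformed Gaussian and second-degree polynomial kernels on this kind
#' of spectra); feature columns are standardized internally before margin
#' fitting so the cost scale is comparable across feature schemes, and the
#' same transform is applied at prediction. KNN defaults to k = 3
#' Euclidean on the raw features. `class_order` is fixed at
#' fit time (factor levels if `labels` is a factor, otherwise sorted unique
#' labels) and predictions never leave it.
#'
#' @param x Numeric feature matrix, one row per spectrum.
#' @param labels Class labels (character or factor), one per row.
#' @param scheme Optional [feature_scheme()] recorded in the model (used by
#'   the streaming classifier to featurize incoming spectra).
#' @param kind `"svm"` or `"knn"`.
#' @param svm_kernel `"linear"` (default), `"rbf"` or `"poly2"`.
#' @param cost SVM regularization constant (default 1).
#' @param knn_k Neighbor count (default 3).
#' @param knn_metric `"euclidean"` (default), `"manhattan"` or
#'   `"mahalanobis"` (covariance ridged for stability when p >= n).
#' @param preprocess Optional [preprocess_config()] recorded as provenance.
#' @param seed Optional seed applied around fitting (libsvm and the KNN
#'   store are deterministic; the seed is recorded for provenance).
#' @return An object of class `tissue_classifier`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
#' y <- rep(c("liver", "lung"), each = 20)
#' fit <- tissue_classifier(x, y, kind = "svm")
#' mean(predict(fit, x) == y)
tissue_classifier <- function(x, labels, scheme = NULL,
                              kind = c("svm", "knn"),
                              svm_kernel = c("linear", "rbf", "poly2"),
                              cost = 1,
                              knn_k = 3L,
                              knn_metric = c("euclidean", "manhattan", "mahalanobis"),
                              preprocess = NULL, seed = NULL) {
  kind <- match.arg(kind)
  svm_kernel <- match.arg(svm_kernel)
  knn_metric <- match.arg(knn_metric)
  x <- as.matrix(x)
  ns_assert(nrow(x) == length(labels), "rows of x must match labels", "training_error")
  ns_assert(all(is.finite(x)), "non-finite feature values", "training_error")
  class_order <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  ns_assert(length(unique(labels)) >= 2, "need at least 2 classes", "training_error")
  ns_assert(knn_k >= 1, "knn_k must be >= 1", "training_error")

  fit <- with_seed(seed, {
    if (kind == "svm") {
      kern <- switch(svm_kernel, linear = "linear", rbf = "radial", poly2 = "polynomial")
      # standardize columns so the margin/cost scale is comparable across
      # feature schemes (slope features are ~1e-3 per nm, full-range ~1e-1)
      mu <- colMeans(x)
      sg <- apply(x, 2, stats::sd)
      sg[!is.finite(sg) | sg < 1e-12] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
      present <- intersect(class_order, unique(labels))
      machines <- lapply(present, function(cl) {
        y <- factor(ifelse(labels == cl, "target", "rest"), levels = c("target", "rest"))
        args <- list(x = xs, y = y, kernel = kern, cost = cost, scale = FALSE)
        if (svm_kernel == "poly2") { args$degree <- 2; args$coef0 <- 1 }
        do.call(e1071::svm, args)
      })
      names(machines) <- present
      list(machines = machines, center = mu, scale = sg)
    } else {
      inv_cov <- NULL
      if (knn_metric == "mahalanobis") {
        cv <- stats::cov(x)
        ridge <- 1e-6 * mean(diag(cv)) + 1e-12
        inv_cov <- solve(cv + diag(ridge, ncol(cv)))
      }
      list(train_x = x, train_y = labels, inv_cov = inv_cov)
    }
  })

  structure(list(kind = kind, scheme = scheme, class_order = class_order,
                 svm_kernel = svm_kernel, cost = cost,
                 knn_k = as.integer(knn_k), knn_metric = knn_metric,
                 preprocess = preprocess, seed = seed,
                 n_features = ncol(x), n_train = nrow(x), fit = fit),
            class = "tissue_classifier")
}

#' @export
print.tissue_classifier <- function(x, ...) {
  what <- if (x$kind == "svm")
    sprintf("SVM (%s kernel, cost %g, one-vs-rest)", x$svm_kernel, x$cost)
  else
    sprintf("KNN (k = %d, %s distance)", x$knn_k, x$knn_metric)
  cat(sprintf("Tissue classifier: %s\n", what))
  cat(sprintf("  %d classes, %d features, %d training spectra\n",
              length(x$class_order), x$n_features, x$n_train))
  if (!is.null(x$scheme)) cat("  scheme: ", x$scheme$name, "\n", sep = "")
  invisible(x)
}

#' @export
summary.tissue_classifier <- function(object, ...) {
  print(object)
  cat("  classes:", paste(object$class_order, collapse = ", "), "\n")
  if (object$kind == "svm") {
    nsv <- vapply(object$fit$machines, function(m) m$tot.nSV, numeric(1))
    cat("  support vectors per one-vs-rest machine:\n")
    for (cl in names(nsv)) cat(sprintf("    %-8s %d\n", cl, nsv[[cl]]))
  }
  invisible(object)
}

# Pairwise distances between query rows and training rows.
knn_distances <- function(q, x, metric, inv_cov = NULL) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(q^2), rowSums(x^2), "+") - 2 * tcrossprod(q, x)
    sqrt(pmax(d2, 0))
  } else if (metric == "manhattan") {
    t(apply(q, 1, function(r) colSums(abs(t(x) - r))))
  } else {
    diff2 <- function(r) { d <- t(x) - r; sqrt(pmax(colSums((inv_cov %*% d) * d), 0)) }
    t(apply(q, 1, diff2))
  }
}

# Raw per-class decision matrix (SVM) or vote counts (KNN), n x K.
decision_matrix <- function(model, x) {
  K <- length(model$class_order)
  out <- matrix(0, nrow(x), K, dimnames = list(NULL, model$class_order))
  if (model$kind == "svm") {
    x <- sweep(sweep(x, 2, model$fit$center), 2, model$fit$scale, "/")
    for (cl in names(model$fit$machines)) {
      p <- stats::predict(model$fit$machines[[cl]], x, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      # libsvm signs the margin toward whichever class it saw first in the
      # training data; the column name records the orientation
      s <- if (identical(colnames(dv), "rest/target")) -1 else 1
      out[, cl] <- s * as.numeric(dv)
    }
    out[, setdiff(model$class_order, names(model$fit$machines))] <- -Inf
  } else {
    D <- knn_distances(x, model$fit$train_x, model$knn_metric, model$fit$inv_cov)
    k <- min(model$knn_k, ncol(D))
    for (i in seq_len(nrow(x))) {
      nn <- order(D[i, ])[seq_len(k)]
      votes <- table(factor(model$fit$train_y[nn], levels = model$class_order))
      out[i, ] <- as.numeric(votes)
    }
  }
  out
}

#' Per-class classification scores
#'
#' Returns one normalized, nonnegative score vector per row, summing to 1,
#' whose argmax is the predicted class. For KNN the scores are neighbor
#' vote fractions; for SVM they are a fixed monotone normalization
#' (softmax) of the per-class one-vs-rest decision values. These are the
#' quantities averaged when classifiers are combined.
#'
#' @param model A `tissue_classifier`.
#' @param x Feature matrix matching the model's scheme.
#' @return Numeric matrix, rows x classes, each row summing to 1.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "tissue_classifier"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    ns_stop(sprintf("feature dimension %d does not match model (%d)",
                    ncol(x), model$n_features), "inference_error")
  D <- decision_matrix(model, x)
  if (model$kind == "svm") {
    # row-wise softmax: fixed monotone map of decision values
    D <- exp(D - apply(D, 1, max))
    D / rowSums(D)
  } else {
    D / rowSums(D)
  }
}

#' Predict classes (or scores) from a tissue classifier
#'
#' For SVM, the predicted class is the argmax of the one-vs-rest decision
#' values. For KNN it is the neighbor majority; vote ties are broken by the
#' class of the single nearest neighbor among the tied classes.
#'
#' @param object A `tissue_classifier`.
#' @param x Feature matrix.
#' @param type `"class"` (default) or `"score"`.
#' @param ... Unused.
#' @return Character vector of labels, or the score matrix.
#' @export
predict.tissue_classifier <- function(object, x, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (type == "score") return(predict_scores(object, x))
  if (ncol(x) != object$n_features)
    ns_stop(sprintf("feature dimension %d does not match model (%d)",
                    ncol(x), object$n_features), "inference_error")
  D <- decision_matrix(object, x)
  out <- character(nrow(x))
  if (object$kind == "knn") {
    dist <- knn_distances(x, object$fit$train_x, object$knn_metric, object$fit$inv_cov)
  }
  for (i in seq_len(nrow(x))) {
    top <- which(D[i, ] == max(D[i, ]))
    if (length(top) == 1L || object$kind == "svm") {
      out[i] <- object$class_order[top[1]]
    } else {
      # KNN vote tie: the nearest neighbor belonging to a tied class decides
      tied <- object$class_order[top]
      ord <- order(dist[i, ])
      nn_cls <- object$fit$train_y[ord]
      out[i] <- nn_cls[nn_cls %in% tied][1]
    }
  }
  out
}

#' Combine classifiers by score averaging
#'
#' Builds an ensemble whose score vector is the arithmetic mean of the
#' members' score vectors; the prediction is its argmax, with exact ties
#' broken toward the earlier class in `class_order`. All members must share
#' the same class order. A single-member combination is exactly that model.
#'
#' @param models List of `tissue_classifier`s.
#' @return An object of class `tissue_ensemble`.
#' @export
combine_models <- function(models) {
  ns_assert(length(models) >= 1, "need at least one model", "combination_error")
  for (m in models) stopifnot(inherits(m, "tissue_classifier"))
  co <- models[[1]]$class_order
  same <- vapply(models, function(m) identical(m$class_order, co), logical(1))
  if (!all(same)) ns_stop("members disagree on class_order", "combination_error")
  structure(list(models = models, class_order = co), class = "tissue_ensemble")
}

#' @export
print.tissue_ensemble <- function(x, ...) {
  cat(sprintf("Score-averaging ensemble of %d classifiers\n", length(x$models)))
  for (m in x$models)
    cat(sprintf("  - %s / %s\n", m$kind,
                if (is.null(m$scheme)) "?" else m$scheme$name))
  invisible(x)
}

#' @rdname predict_scores
#' @param feature_list For an ensemble: list of feature matrices, one per
#'   member, in member order (members may use different schemes).
#' @export
predict_scores_ensemble <- function(model, feature_list) {
  stopifnot(inherits(model, "tissue_ensemble"))
  ns_assert(length(feature_list) == length(model$models),
            "need one feature matrix per ensemble member", "combination_error")
  S <- predict_scores(model$models[[1]], feature_list[[1]])
  if (length(model$models) > 1)
    for (j in 2:length(model$models))
      S <- S + predict_scores(model$models[[j]], feature_list[[j]])
  S / length(model$models)
}

#' @export
predict.tissue_ensemble <- function(object, feature_list,
                                    type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "class" && length(object$models) == 1L)
    return(predict(object$models[[1]], feature_list[[1]]))  # exact identity
  S <- predict_scores_ensemble(object, feature_list)
  if (type == "score") return(S)
  # ties break toward the earlier entry in class_order (which.max is first-max)
  object$class_order[apply(S, 1, which.max)]
}

#' Stratified k-fold split
#'
#' Partitions indices into k folds so that each class's members are spread
#' as evenly as possible: per-class validation counts differ by at most one
#' across folds, and extras go to the currently smallest folds so overall
#' fold sizes also differ by at most one. Deterministic under `seed`.
#'
#' @param labels Class labels, one per sample.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the within-class shuffles.
#' @return List of k elements, each `list(fold_id, train, validation)`;
#'   validation sets partition `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = NULL) {
  labels <- as.character(labels)
  k <- as.integer(k)
  ns_assert(k >= 2, "k must be >= 2", "argument_error")
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small))
    ns_stop(paste0("class(es) with fewer than k members: ",
                   paste(small, collapse = ", ")), "argument_error")
  val <- vector("list", k)
  with_seed(seed, {
    fold_sizes <- integer(k)
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      # folds currently smallest take the extra samples (ties: fold order)
      gets_extra <- order(fold_sizes, seq_len(k))[seq_len(extra)]
      sizes <- rep(base, k)
      sizes[gets_extra] <- base + 1L
      stops <- cumsum(sizes)
      starts <- c(1L, utils::head(stops, -1) + 1L)
      for (f in seq_len(k))
        if (sizes[f] > 0) val[[f]] <- c(val[[f]], idx[starts[f]:stops[f]])
      fold_sizes <- fold_sizes + sizes
    }
  })
  all_idx <- seq_along(labels)
  lapply(seq_len(k), function(f)
    list(fold_id = f, train = setdiff(all_idx, val[[f]]),
         validation = sort(val[[f]])))
}

#' Subject-independent holdout split
#'
#' Splits a manifest into training and test row indices such that no
#' subject contributes to both sides.
#'
#' @param manifest A `dataset_manifest` (or data frame with `subject_id`).
#' @param held_out_subjects Character vector of subject ids to hold out.
#' @return `list(train = indices, test = indices)`.
#' @export
subject_holdout_split <- function(manifest, held_out_subjects) {
  subj <- as.character(manifest$subject_id)
  unknown <- setdiff(held_out_subjects, unique(subj))
  if (length(unknown))
    ns_stop(paste0("unknown subject(s): ", paste(unknown, collapse = ", ")),
            "argument_error")
  test <- which(subj %in% held_out_subjects)
  train <- setdiff(seq_along(subj), test)
  if (length(train) == 0)
    ns_stop("holding out all subjects leaves an empty training set", "argument_error")
  list(train = train, test = test)
}

#' Classifier specifications for cross-validation
#'
#' The eight canonical classifiers: SVM and KNN on each of the four feature
#' schemes, with the default hyperparameters (linear kernel, cost 1;
#' k = 3 Euclidean).
#'
#' @param decimation Decimation factor for the full scheme (default 2,
#'   halving the restricted spectrum).
#' @return Named list of classifier specifications, each
#'   `list(kind, scheme_name, ...)`.
#' @export
default_classifiers <- function(decimation = 2L) {
  schemes <- c("full", "band", "point", "slope")
  out <- list()
  for (kind in c("svm", "knn"))
    for (sc in schemes)
      out[[paste(kind, sc, sep = "_")]] <-
        list(kind = kind, scheme_name = sc, decimation = decimation)
  out
}

scheme_from_spec <- function(spec) {
  feature_scheme(spec$scheme_name,
                 decimation = if (is.null(spec$decimation)) 1L else spec$decimation)
}

fit_from_spec <- function(spec, x, labels, scheme = NULL, seed = NULL) {
  tissue_classifier(
    x, labels, scheme = scheme, kind = spec$kind,
    svm_kernel = if (is.null(spec$svm_kernel)) "linear" else spec$svm_kernel,
    cost = if (is.null(spec$cost)) 1 else spec$cost,
    knn_k = if (is.null(spec$knn_k)) 3L else spec$knn_k,
    knn_metric = if (is.null(spec$knn_metric)) "euclidean" else spec$knn_metric,
    seed = seed)
}

#' Stratified cross-validation of classifiers and combinations
#'
#' Runs stratified k-fold CV over any set of classifiers (and optionally
#' score-averaged combinations of them), returning a fold-by-classifier
#' accuracy table with an `Average` row, ranked by mean accuracy.
#'
#' @param features_by_scheme Named list of feature matrices (names `full`,
#'   `band`, `point`, `slope` as used by the classifier specs), all with
#'   the same row order.
#' @param labels Class labels, one per row.
#' @param classifiers Named list of classifier specs (see
#'   [default_classifiers()]).
#' @param combinations Optional named list of character vectors, each
#'   naming member classifiers to combine by score averaging.
#' @param k Folds (default 5).
#' @param seed Seed for the fold split.
#' @return A `data.frame` of class `cv_table`: one row per fold plus an
#'   `Average` row, one column per classifier/combination, attribute
#'   `ranking` with classifiers ordered by decreasing mean accuracy.
#' @export
cross_validate <- function(features_by_scheme, labels, classifiers = default_classifiers(),
                           combinations = NULL, k = 5L, seed = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  for (f in features_by_scheme)
    ns_assert(nrow(f) == n, "feature matrices must match labels", "argument_error")
  folds <- stratified_kfold(labels, k = k, seed = seed)
  cols <- c(names(classifiers), names(combinations))
  acc <- matrix(NA_real_, k, length(cols), dimnames = list(NULL, cols))

  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; va <- folds[[f]]$validation
    truth <- labels[va]
    models <- list()
    for (nm in names(classifiers)) {
      spec <- classifiers[[nm]]
      X <- features_by_scheme[[spec$scheme_name]]
      models[[nm]] <- fit_from_spec(spec, X[tr, , drop = FALSE],
                                    factor(labels[tr], levels = sort(unique(labels))),
                                    seed = seed)
      pred <- predict(models[[nm]], X[va, , drop = FALSE])
      acc[f, nm] <- mean(pred == truth)
    }
    for (nm in names(combinations)) {
      members <- combinations[[nm]]
      ens <- combine_models(models[members])
      fl <- lapply(members, function(mn)
        features_by_scheme[[classifiers[[mn]]$scheme_name]][va, , drop = FALSE])
      acc[f, nm] <- mean(predict(ens, fl) == truth)
    }
  }
  out <- as.data.frame(rbind(acc, colMeans(acc)))
  out <- cbind(fold = c(as.character(seq_len(k)), "Average"), out)
  rownames(out) <- NULL
  attr(out, "ranking") <- names(sort(colMeans(acc), decreasing = TRUE))
  class(out) <- c("cv_table", "data.frame")
  out
}

#' @export
print.cv_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round_half_up, digits = digits)
  print.data.frame(y, row.names = FALSE)
  rk <- attr(x, "ranking")
  if (!is.null(rk))
    cat("Ranking by mean accuracy:", paste(rk, collapse = " > "), "\n")
  invisible(x)
}
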