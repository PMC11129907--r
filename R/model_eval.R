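# RBF-kernel SVM training (one-vs-one, SMO solver), dual evaluation
# (in-sample test split and the discarded real-sample pool), and the 2-D
# PCA embedding of the selected-feature space.

#' Random train/test split
#'
#' @param n Number of rows (or a `resampled_dataset`, whose row count is
#'   used).
#' @param train_frac Fraction assigned to training (default 0.75); train
#'   size is `round(train_frac * n)`.
#' @param seed Integer seed.
#' @return List `train` and `test` of disjoint row indices covering `1:n`.
#' @export
train_test_split <- function(n, train_frac = 0.75, seed = 1L) {
  if (inherits(n, "resampled_dataset")) n <- nrow(n$matrix)
  set.seed(seed)
  n_train <- round(train_frac * n)
  tr <- sort(sample.int(n, n_train))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Train a one-vs-one RBF-kernel SVM
#'
#' Features are z-scored with training-set statistics; one binary SVM is
#' fitted per class pair with an SMO solver; prediction is by majority vote
#' with ties broken by the summed decision values. `gamma` defaults to
#' `1 / (d * var)` with `d` the feature count and `var` the overall variance
#' of the standardised training matrix (so approximately `1/d`).
#'
#' @param X Numeric training matrix (rows = samples, named columns).
#' @param y Integer class labels (at least 2 distinct values).
#' @param C Soft-margin cost (default 1).
#' @param gamma RBF width; `NULL` for the default above.
#' @return A `trained_svm`: standardisation parameters, per-pair dual
#'   solutions, hyperparameters, class set, feature names, and the number
#'   of support vectors per pair.
#' @export
train_svm <- function(X, y, C = 1, gamma = NULL) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training set must contain at least 2 classes")
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  if (is.null(gamma)) gamma <- 1 / (ncol(Xs) * stats::var(as.vector(Xs)))
  pairs <- utils::combn(classes, 2)
  models <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    c1 <- pairs[1, p]; c2 <- pairs[2, p]
    idx <- which(y %in% c(c1, c2))
    yb <- ifelse(y[idx] == c1, 1L, -1L)
    fit <- smo_train_cpp(Xs[idx, , drop = FALSE], yb, C, gamma)
    sv <- fit$alpha > 1e-12
    models[[p]] <- list(classes = c(c1, c2), X = Xs[idx, , drop = FALSE][sv, , drop = FALSE],
                        y = yb[sv], alpha = fit$alpha[sv], rho = fit$rho,
                        n_sv = sum(sv))
  }
  structure(list(mu = mu, sd = sdev, gamma = gamma, C = C, classes = classes,
                 feature_names = colnames(X), pair_models = models),
            class = "trained_svm")
}

#' Predict severity labels with a trained SVM
#'
#' @param object A `trained_svm`.
#' @param newdata Matrix whose column names match the training features
#'   (checked; mismatching schemas are refused).
#' @param ... Unused.
#' @return Integer vector of predicted labels.
#' @export
predict.trained_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(newdata)) ||
        !identical(colnames(newdata), object$feature_names)) {
      stop("feature names/ordering of `newdata` do not match the model schema")
    }
  }
  Xs <- sweep(sweep(newdata, 2, object$mu), 2, object$sd, "/")
  nc <- length(object$classes)
  votes <- matrix(0, nrow(Xs), nc, dimnames = list(NULL, object$classes))
  score <- matrix(0, nrow(Xs), nc, dimnames = list(NULL, object$classes))
  for (m in object$pair_models) {
    f <- svm_decision_cpp(m$X, m$y, m$alpha, m$rho, object$gamma, Xs)
    w1 <- as.character(m$classes[1]); w2 <- as.character(m$classes[2])
    votes[, w1] <- votes[, w1] + (f >= 0)
    votes[, w2] <- votes[, w2] + (f < 0)
    score[, w1] <- score[, w1] + f
    score[, w2] <- score[, w2] - f
  }
  # majority vote; ties broken by summed decision value, then lower class
  out <- integer(nrow(Xs))
  for (i in seq_len(nrow(Xs))) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) best <- best[which.max(score[i, best])]
    out[i] <- object$classes[best[1]]
  }
  out
}

#' Build an evaluation report from true and predicted labels
#'
#' @param truth,pred Integer label vectors in `{0, 1, 2}`.
#' @param dataset_id Identifier stored in the report (e.g.
#'   `"in_sample_test"` or `"discarded_pool"`).
#' @return An `eval_report`: 3x3 confusion matrix (`confusion`, rows =
#'   truth) and its row-normalised form, `accuracy`, `sensitivity`
#'   (any-tremor detection: predicted >= 1 given true >= 1), `per_class_accuracy`,
#'   `adjacent_misclass_rate` and `nonadjacent_misclass_rate` (fractions of
#'   all samples misclassified into an adjacent / non-adjacent class),
#'   `n`, `absent_classes`, `dataset_id`.
#' @export
eval_report <- function(truth, pred, dataset_id = "in_sample_test") {
  if (!length(truth)) stop("empty evaluation input")
  if (length(truth) != length(pred)) stop("truth/pred length mismatch")
  lv <- 0:2
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.numeric(cm), 3, 3, dimnames = list(truth = lv, pred = lv))
  rs <- rowSums(cm)
  norm <- cm / ifelse(rs > 0, rs, 1)
  n <- length(truth)
  trem <- truth >= 1
  sens <- if (any(trem)) mean(pred[trem] >= 1) else NA_real_
  per_class <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  dd <- abs(truth - pred)
  structure(list(
    confusion = cm, confusion_normalized = norm,
    accuracy = sum(diag(cm)) / n,
    sensitivity = sens,
    per_class_accuracy = per_class,
    adjacent_misclass_rate = mean(dd == 1),
    nonadjacent_misclass_rate = mean(dd == 2),
    n = n,
    absent_classes = lv[rs == 0],
    dataset_id = dataset_id
  ), class = "eval_report")
}

#' Evaluate a trained SVM on a labelled matrix
#'
#' @param model A `trained_svm`.
#' @param X Feature matrix matching the model schema.
#' @param y True labels.
#' @param dataset_id Report identifier.
#' @return An [eval_report()].
#' @export
evaluate <- function(model, X, y, dataset_id = "in_sample_test") {
  if (!nrow(as.matrix(X))) stop("empty evaluation input")
  eval_report(y, predict(model, X), dataset_id)
}

#' Evaluate a trained SVM on the discarded real-sample pool
#'
#' The rows removed by undersampling were used in feature selection but in
#' neither training nor testing; classifying them probes out-of-sample
#' behaviour on exclusively real data. The report's `absent_classes` field
#' notes classes with no pool representatives (typically the
#' SMOTE-oversampled minority).
#'
#' @param model A `trained_svm`.
#' @param ds A `resampled_dataset` with a non-empty discarded pool.
#' @return An [eval_report()] with `dataset_id = "discarded_pool"`.
#' @export
evaluate_discarded <- function(model, ds) {
  if (!nrow(ds$discarded)) stop("discarded pool is empty")
  evaluate(model, ds$discarded, ds$discarded_labels, "discarded_pool")
}

#' 2-D PCA embedding fitted on the initial dataset
#'
#' Loadings are fitted once on the initial (pre-resampling) selected-feature
#' matrix (centred and unit-scaled); the identical transformation is applied
#' to any further matrix, e.g. the resampled dataset, so both live in the
#' same coordinate system.
#'
#' @param fit_X Matrix the loadings are fitted on (the initial dataset
#'   restricted to the selected features).
#' @param transform_X Optional matrix to project with the fitted loadings
#'   (defaults to `fit_X`).
#' @param n_components Number of components (default 2).
#' @param synthetic Optional logical flag per row of `transform_X`, carried
#'   into the output for plotting.
#' @return List `coords` (n x n_components), `rotation`, `center`, `scale`,
#'   `sdev`, and `synthetic`.
#' @export
pca_embedding <- function(fit_X, transform_X = NULL, n_components = 2,
                          synthetic = NULL) {
  fit_X <- as.matrix(fit_X)
  if (n_components > ncol(fit_X)) stop("n_components exceeds the feature count")
  sc <- apply(fit_X, 2, stats::sd)
  pc <- stats::prcomp(fit_X, center = TRUE, scale. = all(sc > 1e-12))
  if (is.null(transform_X)) transform_X <- fit_X
  coords <- stats::predict(pc, as.matrix(transform_X))[, seq_len(n_components), drop = FALSE]
  list(coords = coords,
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center, scale = pc$scale, sdev = pc$sdev,
       synthetic = synthetic)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation on", x$dataset_id, "(n =", x$n, ")\n")
  cat(sprintf("  accuracy: %.3f  tremor sensitivity: %.3f\n",
              x$accuracy, x$sensitivity))
  print(x$confusion)
  invisible(x)
}
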