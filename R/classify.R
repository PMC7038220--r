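#' Probabilistic neural network (Parzen-window) classifier
#'
#' The class score of a point x is the average isotropic Gaussian kernel to
#' that class's training points,
#' `score_c(x) = (1/n_c) sum_i exp(-||x - x_i||^2 / (2 sigma^2))`,
#' and the prediction is the argmax. As sigma -> 0 the classifier degenerates
#' to 1-nearest-neighbor; as sigma -> Inf all kernels flatten and the
#' majority class wins (ties resolved toward the first class level).
#'
#' @param X Training matrix, n x d.
#' @param y Class labels (ties in prediction break toward the first level).
#' @param sigma Parzen kernel width (> 0), in the units of X.
#' @return A `pnn` model.
#' @export
pnn_fit <- function(X, y, sigma) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stopf("PNN needs training examples from at least two classes")
  sigma <- assert_number(sigma, "sigma", lo = .Machine$double.xmin)
  structure(list(X = X, y = y, sigma = sigma), class = "pnn")
}

#' @rdname pnn_fit
#' @param object A fitted `pnn`.
#' @param newdata Matrix of points to classify.
#' @param type "class" for labels, "score" for the per-class Parzen sums.
#' @param ... Unused.
#' @export
predict.pnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stopf("newdata has %d columns, model expects %d", ncol(newdata), ncol(object$X))
  lv <- levels(object$y)
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2a.b
  d2 <- outer(rowSums(newdata^2), rowSums(object$X^2), `+`) -
    2 * tcrossprod(newdata, object$X)
  d2 <- pmax(d2, 0)
  class_means <- function(Kmat) {
    s <- vapply(lv, function(cl)
      rowMeans(Kmat[, object$y == cl, drop = FALSE]), numeric(nrow(newdata)))
    matrix(s, nrow = nrow(newdata), dimnames = list(NULL, lv))
  }
  if (type == "score")
    return(class_means(exp(-d2 / (2 * object$sigma^2))))
  # prediction: shift distances per test point so the kernels cannot all
  # underflow (a common positive factor per row preserves the argmax), and
  # weight the class densities by the training priors n_c/n
  shift <- apply(d2, 1L, min)
  dens <- class_means(exp(-(d2 - shift) / (2 * object$sigma^2)))
  priors <- as.numeric(table(object$y)[lv]) / length(object$y)
  post <- sweep(dens, 2L, priors, `*`)
  factor(lv[max.col(post, ties.method = "first")], levels = lv)
}

#' Classifier specification
#'
#' @param kind One of "pnn", "lda", "qda", "knn", "svm_poly1", "svm_poly2",
#'   "svm_poly3", "svm_rbf".
#' @param pnn_sigma PNN kernel width; NULL (default) grid-searches
#'   multipliers 0.01..10 (log-spaced) of the median pairwise training
#'   distance on inner folds.
#' @param knn_k Neighborhood size for kNN (default 5).
#' @param svm_cost SVM cost parameter C (default 1).
#' @param svm_gamma SVM kernel gamma; NULL uses 1/n_features.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("pnn", "lda", "qda", "knn", "svm_poly1",
                                     "svm_poly2", "svm_poly3", "svm_rbf"),
                            pnn_sigma = NULL, knn_k = 5L, svm_cost = 1,
                            svm_gamma = NULL) {
  kind <- match.arg(kind)
  if (!is.null(pnn_sigma)) pnn_sigma <- assert_number(pnn_sigma, "pnn_sigma", lo = 1e-300)
  structure(list(kind = kind, pnn_sigma = pnn_sigma,
                 knn_k = assert_count(knn_k, "knn_k"),
                 svm_cost = assert_number(svm_cost, "svm_cost", lo = 1e-12),
                 svm_gamma = svm_gamma),
            class = "classifier_spec")
}

pnn_pick_sigma <- function(X, y, seed = 1L) {
  dists <- as.numeric(stats::dist(X))
  med <- stats::median(dists[dists > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  grid <- med * 10^seq(-2, 1, length.out = 13)
  folds <- make_folds(y, n_folds = min(5L, min(table(y))), seed = seed)
  acc <- vapply(grid, function(sg) {
    hits <- 0L
    for (f in unique(folds)) {
      te <- folds == f
      if (nlevels(droplevels(y[!te])) < 2L) next
      mod <- pnn_fit(X[!te, , drop = FALSE], y[!te], sg)
      hits <- hits + sum(predict(mod, X[te, , drop = FALSE]) == y[te])
    }
    hits
  }, integer(1))
  grid[which.max(acc)]   # smallest sigma wins ties
}

#' Build a classifier with a uniform fit/predict contract
#'
#' PNN is implemented in this package; LDA/QDA delegate to MASS, kNN to
#' class::knn, and the SVM variants to e1071 (polynomial kernels of degree
#' 1-3 with coef0 = 1, or RBF).
#'
#' @param spec A [classifier_spec()].
#' @return List with functions `fit(X, y, seed)` and `predict(model, X)`.
#' @export
make_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  kind <- spec$kind
  if (kind == "pnn") {
    return(list(
      fit = function(X, y, seed = 1L) {
        sg <- spec$pnn_sigma %||% pnn_pick_sigma(as.matrix(X), as.factor(y), seed)
        pnn_fit(X, y, sg)
      },
      predict = function(model, X) predict(model, X)))
  }
  if (kind %in% c("lda", "qda")) {
    fitfun <- if (kind == "lda") MASS::lda else MASS::qda
    return(list(
      fit = function(X, y, seed = 1L) fitfun(as.matrix(X), grouping = as.factor(y)),
      predict = function(model, X) stats::predict(model, as.matrix(X))$class))
  }
  if (kind == "knn") {
    return(list(
      fit = function(X, y, seed = 1L) list(X = as.matrix(X), y = as.factor(y)),
      predict = function(model, X)
        class::knn(model$X, as.matrix(X), model$y, k = spec$knn_k)))
  }
  if (grepl("^svm", kind)) {
    return(list(
      fit = function(X, y, seed = 1L) {
        X <- as.matrix(X)
        gamma <- spec$svm_gamma %||% (1 / ncol(X))
        if (kind == "svm_rbf") {
          e1071::svm(X, as.factor(y), kernel = "radial", cost = spec$svm_cost,
                     gamma = gamma, scale = FALSE)
        } else {
          e1071::svm(X, as.factor(y), kernel = "polynomial",
                     degree = as.integer(sub("svm_poly", "", kind)),
                     coef0 = 1, gamma = gamma, cost = spec$svm_cost,
                     scale = FALSE)
        }
      },
      predict = function(model, X) stats::predict(model, as.matrix(X))))
  }
  stopf("unknown classifier kind '%s'", kind)
}

#' Classification metrics from pooled confusion counts
#'
#' Accuracy, sensitivity (recall of the positive class), specificity and
#' positive predictive value, all in percent. Ratios with a zero denominator
#' are reported as NA, never as 0.
#'
#' @param TP,FN,TN,FP Non-negative integer counts (positive class = ASD by
#'   package convention).
#' @return Named numeric vector (accuracy, sensitivity, specificity, ppv).
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  TP <- unname(TP); FN <- unname(FN); TN <- unname(TN); FP <- unname(FP)
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stopf("all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(accuracy = 100 * (TP + TN) / total,
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    ppv = ratio(TP, TP + FP))
}

# Stratified fold assignment: shuffle within class, deal round-robin.
make_folds <- function(y, n_folds, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(as.factor(y))) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation with pooled confusion counts
#'
#' Folds are stratified by class (and kept group-disjoint when `group_ids`
#' is given, e.g. multiple segments per subject). Held-out predictions are
#' pooled into a single confusion table (micro-average) from which the four
#' metrics are computed. If a random fold split leaves a training fold with
#' one class, the split is redrawn with a new derived seed (logged).
#'
#' @param X Feature matrix, n x m.
#' @param y Two-class labels.
#' @param spec A [classifier_spec()].
#' @param n_folds Number of folds (default 10).
#' @param seed Seed controlling the fold assignment (and any inner tuning).
#' @param group_ids Optional grouping; all rows of a group land in one fold.
#' @param positive Positive class label; defaults to "asd" when present,
#'   else the second factor level.
#' @return `cv_result`: pooled counts TP/FN/TN/FP, per-fold counts, metrics,
#'   `n_features_used`, fold assignment, seed.
#' @export
cross_validate <- function(X, y, spec, n_folds = 10L, seed = 1L,
                           group_ids = NULL, positive = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("two-class labels required")
  n_folds <- assert_count(n_folds, "n_folds", min = 2L)
  positive <- positive %||% (if ("asd" %in% levels(y)) "asd" else levels(y)[2])
  if (!positive %in% levels(y)) stopf("positive class '%s' not in labels", positive)
  if (is.null(group_ids)) group_ids <- seq_along(y)
  groups <- unique(group_ids)
  gclass <- y[match(groups, group_ids)]
  if (n_folds > min(table(gclass)))
    stopf("n_folds = %d exceeds the smaller class count (%d groups)",
          n_folds, min(table(gclass)))

  clf <- if (inherits(spec, "classifier_spec")) make_classifier(spec)
         else if (is.list(spec) && is.function(spec$fit) && is.function(spec$predict)) spec
         else stopf("`spec` must be a classifier_spec or a fit/predict pair")
  attempt_seed <- seed
  for (attempt in 1:10) {
    gfolds <- make_folds(gclass, n_folds, seed = attempt_seed)
    folds <- gfolds[match(group_ids, groups)]
    ok <- all(vapply(seq_len(n_folds), function(f)
      nlevels(droplevels(y[folds != f])) == 2L, logical(1)))
    if (ok) break
    message(sprintf("cross_validate: fold split %d left a one-class training set; redrawing", attempt))
    attempt_seed <- derive_seed(attempt_seed, attempt)
  }
  per_fold <- matrix(0L, n_folds, 4L,
                     dimnames = list(NULL, c("TP", "FN", "TN", "FP")))
  pred_all <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in seq_len(n_folds)) {
    te <- folds == f
    model <- clf$fit(X[!te, , drop = FALSE], y[!te],
                     seed = derive_seed(seed, 100L + f))
    pred <- clf$predict(model, X[te, , drop = FALSE])
    pred <- factor(as.character(pred), levels = levels(y))
    pred_all[te] <- pred
    pos <- y[te] == positive
    per_fold[f, ] <- c(sum(pred[pos] == positive), sum(pred[pos] != positive),
                       sum(pred[!pos] != positive), sum(pred[!pos] == positive))
  }
  pooled <- colSums(per_fold)
  structure(list(
    pooled = pooled, per_fold = per_fold,
    metrics = confusion_metrics(pooled["TP"], pooled["FN"], pooled["TN"],
                                pooled["FP"]),
    n_features_used = ncol(X), n_folds = n_folds, seed = seed,
    positive = positive, folds = folds, predictions = pred_all),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "%d-fold CV (%d features): acc %.2f%%, sens %.2f%%, spec %.2f%%, ppv %.2f%%\n",
    x$n_folds, x$n_features_used, m["accuracy"], m["sensitivity"],
    m["specificity"], m["ppv"]))
  cat(sprintf("  pooled counts: TP=%d FN=%d TN=%d FP=%d (positive = %s)\n",
              x$pooled["TP"], x$pooled["FN"], x$pooled["TN"], x$pooled["FP"],
              x$positive))
  invisible(x)
}

#' Cross-validated accuracy as a function of the number of top features
#'
#' Runs [cross_validate()] on the top-m ranked features for m = 1..M and
#' reports the full curve plus the best m (smallest m among ties).
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param ranked Ordered column indices (e.g. from [select_features()]).
#' @param spec A [classifier_spec()].
#' @param n_folds,seed,group_ids Passed to [cross_validate()].
#' @return List with `curve` (data.frame m, accuracy) and `best_m`.
#' @export
accuracy_vs_n_features <- function(X, y, ranked, spec, n_folds = 10L,
                                   seed = 1L, group_ids = NULL) {
  if (!length(ranked)) stopf("`ranked` is empty; nothing to evaluate")
  acc <- vapply(seq_along(ranked), function(m) {
    cross_validate(X[, ranked[seq_len(m)], drop = FALSE], y, spec,
                   n_folds = n_folds, seed = seed,
                   group_ids = group_ids)$metrics[["accuracy"]]
  }, numeric(1))
  curve <- data.frame(m = seq_along(ranked), accuracy = acc)
  list(curve = curve, best_m = curve$m[which.max(curve$accuracy)])
}
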