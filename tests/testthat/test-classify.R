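test_that("PNN degenerates to 1-NN for tiny sigma and majority vote for huge sigma", {
  set.seed(51)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- factor(sample(c("a", "b"), 40, replace = TRUE, prob = c(0.3, 0.7)))
    if (nlevels(droplevels(y)) < 2) next
    Xte <- matrix(rnorm(15 * 3), 15, 3)
    scale <- median(dist(X))

    tiny <- predict(pnn_fit(X, y, sigma = 1e-6 * scale), Xte)
    nn1 <- class::knn(X, Xte, y, k = 1)
    expect_equal(as.character(tiny), as.character(nn1))

    huge <- predict(pnn_fit(X, y, sigma = 1e6 * scale), Xte)
    counts <- table(y)
    maj <- names(counts)[which.max(counts)]
    if (counts[1] != counts[2])
      expect_true(all(huge == maj))
    else
      expect_true(all(huge == levels(y)[1]))   # tie resolves to first level
  }
})

test_that("PNN scores equal the closed-form Parzen sums on a 1-D toy", {
  X <- matrix(c(-1, -1.1, -0.9, 1, 1.1, 0.9), ncol = 1)
  y <- factor(rep(c("neg", "pos"), each = 3), levels = c("neg", "pos"))
  m <- pnn_fit(X, y, sigma = 0.1)
  sc <- predict(m, matrix(0.9), type = "score")
  byhand <- function(centers) mean(exp(-(0.9 - centers)^2 / (2 * 0.1^2)))
  expect_equal(unname(sc[1, "neg"]), byhand(c(-1, -1.1, -0.9)), tolerance = 1e-12)
  expect_equal(unname(sc[1, "pos"]), byhand(c(1, 1.1, 0.9)), tolerance = 1e-12)
  expect_gt(sc[1, "pos"] / sc[1, "neg"], 10)
  expect_equal(as.character(predict(m, matrix(0.9))), "pos")
  expect_error(pnn_fit(X, rep("a", 6), 0.1), "two classes")
})

test_that("delegated classifiers satisfy their canonical sanity checks", {
  set.seed(52)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2),
             matrix(rnorm(40, mean = 3, sd = 0.3), 20, 2))
  y <- factor(rep(c("a", "b"), each = 20))
  lin <- make_classifier(classifier_spec("svm_poly1"))
  fit <- lin$fit(X, y)
  expect_equal(mean(lin$predict(fit, X) == y), 1)

  # XOR: not linearly separable, RBF solves it
  Xx <- 2 * rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)) - 1
  Xx <- Xx[rep(1:4, each = 8), ] + matrix(rnorm(64, sd = 0.05), 32, 2)
  yx <- factor(rep(c("a", "b", "b", "a"), each = 8))
  p1 <- make_classifier(classifier_spec("svm_poly1"))
  f1 <- p1$fit(Xx, yx)
  expect_lte(mean(p1$predict(f1, Xx) == yx), 0.75)
  rbf <- make_classifier(classifier_spec("svm_rbf"))
  frbf <- rbf$fit(Xx, yx)
  expect_equal(mean(rbf$predict(frbf, Xx) == yx), 1)

  k1 <- make_classifier(classifier_spec("knn", knn_k = 1))
  fk <- k1$fit(X, y)
  expect_equal(mean(k1$predict(fk, X) == y), 1)

  expect_error(classifier_spec("boost"), "arg")
})

test_that("confusion metrics reproduce the published rows and NA conventions", {
  pnn_row <- confusion_metrics(40, 0, 36, 1)
  expect_equal(round(unname(pnn_row), 2), c(98.70, 100.00, 97.30, 97.56))
  svm2_row <- confusion_metrics(39, 1, 36, 1)
  expect_equal(round(unname(svm2_row), 2), c(97.40, 97.50, 97.30, 97.50))

  none_pos <- confusion_metrics(0, 0, 10, 0)
  expect_true(is.na(none_pos[["sensitivity"]]))
  expect_true(is.na(none_pos[["ppv"]]))
  expect_equal(none_pos[["specificity"]], 100)
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  expect_error(confusion_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("cross-validation pools counts correctly and is seed-deterministic", {
  set.seed(53)
  X <- matrix(rnorm(77 * 2), 77, 2)
  y <- factor(rep(c("normal", "asd"), c(37, 40)), levels = c("normal", "asd"))

  # degenerate classifier that always predicts the majority class
  majority <- list(
    fit = function(X, y, seed = 1L) names(which.max(table(y))),
    predict = function(model, X) rep(model, nrow(X)))
  cv <- cross_validate(X, y, majority, n_folds = 10, seed = 5)
  expect_equal(cv$metrics[["accuracy"]], 100 * 40 / 77, tolerance = 1e-9)
  expect_equal(unname(cv$pooled), c(40L, 0L, 0L, 37L), ignore_attr = TRUE)

  cv2 <- cross_validate(X, y, majority, n_folds = 10, seed = 5)
  expect_identical(cv$folds, cv2$folds)
  # folds partition all samples and are stratified
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_true(all(table(cv$folds) >= 7))

  expect_error(cross_validate(X, y, majority, n_folds = 50, seed = 1),
               "exceeds")
})

test_that("null features give chance-level pooled accuracy across repeats", {
  set.seed(54)
  y <- factor(rep(c("normal", "asd"), c(37, 40)), levels = c("normal", "asd"))
  spec <- classifier_spec("knn", knn_k = 5)
  accs <- vapply(1:20, function(i) {
    X <- matrix(rnorm(77 * 3), 77, 3)
    cross_validate(X, y, spec, n_folds = 10, seed = i)$metrics[["accuracy"]]
  }, numeric(1))
  # mean accuracy within the binomial 95% band around the 40/77 base rate
  band <- 1.96 * sqrt(0.5195 * 0.4805 / (77 * 20)) * 100
  expect_lt(abs(mean(accs) - 51.95), band + 5)
})

test_that("group-aware folds never split a subject's rows", {
  set.seed(55)
  groups <- rep(1:20, each = 3)
  y <- factor(rep(rep(c("a", "b"), each = 10), each = 3))
  X <- matrix(rnorm(60 * 2), 60, 2)
  cv <- cross_validate(X, y, classifier_spec("knn", knn_k = 3), n_folds = 5,
                       seed = 2, group_ids = groups)
  split_count <- tapply(cv$folds, groups, function(f) length(unique(f)))
  expect_true(all(split_count == 1))
})

test_that("accuracy-vs-m curve has one point per feature and ties go to smallest m", {
  set.seed(56)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  perfect <- ifelse(y == "a", -1, 1) + rnorm(n, sd = 0.01)
  noise <- matrix(rnorm(n * 3), n, 3)
  X <- cbind(perfect, noise)
  res <- accuracy_vs_n_features(X, y, ranked = 1:4,
                                classifier_spec("knn", knn_k = 3),
                                n_folds = 5, seed = 3)
  expect_equal(nrow(res$curve), 4)
  expect_equal(res$best_m, res$curve$m[which.max(res$curve$accuracy)])
  expect_equal(res$curve$accuracy[1], 100)
  # adding noise features cannot beat the perfect single feature
  expect_lte(max(res$curve$accuracy), 100)
  expect_equal(res$best_m, 1)
  expect_error(accuracy_vs_n_features(X, y, integer(0),
                                      classifier_spec("knn")), "empty")
})
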