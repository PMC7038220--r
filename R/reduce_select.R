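#' Fit locality sensitive discriminant analysis (LSDA)
#'
#' Supervised linear reduction that preserves local within-class structure
#' while maximizing the local margin between classes. A k-nearest-neighbor
#' graph is split into a within-class adjacency Ww and a between-class
#' adjacency Wb; with Lb = Db - Wb the projection directions a solve the
#' generalized eigenproblem
#'   X' (alpha Lb + (1 - alpha) Ww) X a = lambda X' Dw X a
#' (rows of X are samples, mean-centered internally), keeping the top-d
#' eigenvectors by decreasing eigenvalue. A singular right-hand metric is
#' ridge-regularized automatically (with a message), never silently.
#'
#' @param X Numeric matrix, n_samples x n_features.
#' @param labels Class labels, length n (2 classes required present).
#' @param k Neighborhood size of the kNN graph.
#' @param alpha Between/within trade-off in [0, 1].
#' @param d Reduced dimension; must satisfy d <= min(n_features, n - 1).
#' @param ridge Ridge coefficient added to the right-hand metric when it is
#'   numerically singular; default 1e-8 of its mean diagonal.
#' @param standardize Scale features to unit variance before building the
#'   graph and the eigenproblem (recommended when features have mixed units,
#'   as the 18 texture features do).
#' @param pca_var Fraction of total variance retained by the PCA
#'   pre-projection (default 0.95). Truncating the trailing principal
#'   components regularizes the within-class metric, which is otherwise
#'   singular (and the eigenproblem badly overfit) whenever the feature
#'   count approaches the sample count.
#' @return `lsda_model` with `projection` (n_features x d), `eigenvalues`,
#'   `center`, and the graph matrices `Ww`, `Wb`.
#' @details Before the eigenproblem the (centered) data are projected onto
#'   their principal subspace, as in the published algorithm: when
#'   n_samples < n_features the within-class metric is otherwise singular
#'   and the problem admits spurious null-space directions. `d` greater
#'   than the data rank is clamped to the rank with a message.
#' @export
lsda_fit <- function(X, labels, k = 5L, alpha = 0.5, d = 30L, ridge = 1e-8,
                     standardize = TRUE, pca_var = 0.95) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("feature matrix contains NA")
  n <- nrow(X); D <- ncol(X)
  labels <- as.factor(labels)
  if (length(labels) != n) stopf("labels length != nrow(X)")
  if (nlevels(droplevels(labels)) < 2L)
    stopf("LSDA needs at least two classes present")
  k <- assert_count(k, "k")
  if (k >= n) stopf("`k` must be smaller than the number of samples")
  alpha <- assert_number(alpha, "alpha", 0, 1)
  d <- assert_count(d, "d")
  if (d > min(D, n - 1L))
    stopf("`d` = %d exceeds min(n_features, n_samples - 1) = %d", d, min(D, n - 1L))

  center <- colMeans(X)
  scale_ <- rep(1, D)
  if (standardize) {
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ <= 0] <- 1
  }
  Xc <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)
  # PCA pre-projection: keep the leading principal subspace covering
  # `pca_var` of the variance (never exceeding the data rank)
  pca_var <- assert_number(pca_var, "pca_var", 1e-6, 1)
  sv <- svd(Xc, nu = 0)
  full_rank <- sum(sv$d > max(sv$d) * 1e-10)
  var_frac <- cumsum(sv$d^2) / sum(sv$d^2)
  rank <- min(full_rank, which(var_frac >= pca_var - 1e-12)[1])
  if (d > rank) {
    message(sprintf("LSDA: d reduced from %d to the data rank %d", d, rank))
    d <- rank
  }
  V <- sv$v[, seq_len(rank), drop = FALSE]
  Xc <- Xc %*% V
  # kNN graph with deterministic (index-order) tie-breaking
  dist2 <- as.matrix(stats::dist(Xc))^2
  diag(dist2) <- Inf
  Ww <- matrix(0, n, n); Wb <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dist2[i, ])[seq_len(k)]
    same <- nb[labels[nb] == labels[i]]
    diff <- nb[labels[nb] != labels[i]]
    Ww[i, same] <- 1; Wb[i, diff] <- 1
  }
  Ww <- pmax(Ww, t(Ww)); Wb <- pmax(Wb, t(Wb))
  Dw <- diag(rowSums(Ww), n)
  Lb <- diag(rowSums(Wb), n) - Wb
  M <- crossprod(Xc, (alpha * Lb + (1 - alpha) * Ww) %*% Xc)
  M <- (M + t(M)) / 2
  R <- crossprod(Xc, Dw %*% Xc)
  R <- (R + t(R)) / 2
  mean_diag <- mean(diag(R))
  if (mean_diag <= 0) {
    R <- R + diag(1e-8, rank)
    mean_diag <- 1e-8
    message("LSDA: degenerate within-class metric; ridge applied")
  }
  U <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(U)) {
    message(sprintf("LSDA: singular right-hand metric; ridge %.3g applied",
                    ridge * mean_diag))
    U <- chol(R + diag(ridge * mean_diag, rank))
  }
  # whiten: A = U^-T M U^-1, symmetric eigenproblem
  Ui <- backsolve(U, diag(rank))
  A <- crossprod(Ui, M %*% Ui)
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  # back out of the PCA subspace and fold the feature scaling in
  proj <- (V %*% (Ui %*% eig$vectors[, seq_len(d), drop = FALSE])) / scale_
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(d)) {
    m <- which.max(abs(proj[, j]))
    if (proj[m, j] < 0) proj[, j] <- -proj[, j]
  }
  colnames(proj) <- paste0("LSDA", seq_len(d))
  structure(list(projection = proj, eigenvalues = eig$values[seq_len(d)],
                 center = center, k = k, alpha = alpha, d = d,
                 Ww = Ww, Wb = Wb),
            class = "lsda_model")
}

#' @export
print.lsda_model <- function(x, ...) {
  cat(sprintf("LSDA model: %d features -> %d components (k=%d, alpha=%g)\n",
              nrow(x$projection), x$d, x$k, x$alpha))
  invisible(x)
}

#' Project a feature matrix onto the LSDA basis
#'
#' @param model An [lsda_fit()] model.
#' @param X Matrix with the same feature count the model was fit on.
#' @return n x d matrix with columns named LSDA1..LSDAd.
#' @export
lsda_transform <- function(model, X) {
  stopifnot(inherits(model, "lsda_model"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$projection))
    stopf("X has %d features but the model was fit on %d",
          ncol(X), nrow(model$projection))
  sweep(X, 2L, model$center) %*% model$projection
}

#' Welch two-sample t statistic from group summaries
#'
#' t = |mean2 - mean1| / sqrt(sd1^2/n1 + sd2^2/n2), with Welch-Satterthwaite
#' degrees of freedom and a two-sided p from the t distribution. Reported as
#' a magnitude (the direction of the difference is not retained). When both
#' groups are constant and equal, t is defined as 0 (p = 1).
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (vectorized).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return data.frame with columns `t`, `p`, `df`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) < 0)) stopf("standard deviations must be >= 0")
  if (any(c(n1, n2) < 2)) stopf("group sizes must be >= 2")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  diff <- abs(mean2 - mean1)
  t <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff > 0, Inf, 0))
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(-t, df), 0)
  p[t == 0] <- 1
  data.frame(t = t, p = p, df = df)
}

#' Per-feature Welch t-test ranking of a (reduced) feature matrix
#'
#' Each column is compared between the two label groups with the Welch test;
#' results agree exactly with [welch_t_from_summary()] applied to the
#' column's own group means/SDs. Columns constant in both groups (with equal
#' means) get t = 0, p = 1 and are flagged.
#'
#' @param Z Numeric matrix, n x m (e.g. an LSDA-reduced matrix).
#' @param labels Two-class labels, length n; the first factor level is
#'   group 1.
#' @return `ttest_result`: data.frame with feature, per-group mean/sd, t, p,
#'   df, degenerate flag and rank (1 = smallest p).
#' @export
ttest_rank <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stopf("exactly two classes required")
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stopf("each class needs at least 2 samples")
  m1 <- colMeans(Z[g1, , drop = FALSE])
  m2 <- colMeans(Z[!g1, , drop = FALSE])
  s1 <- apply(Z[g1, , drop = FALSE], 2L, stats::sd)
  s2 <- apply(Z[!g1, , drop = FALSE], 2L, stats::sd)
  w <- welch_t_from_summary(m1, s1, n1, m2, s2, n2)
  feat <- colnames(Z) %||% paste0("V", seq_len(ncol(Z)))
  res <- data.frame(feature = feat, mean1 = m1, sd1 = s1, mean2 = m2,
                    sd2 = s2, t = w$t, p = w$p, df = w$df,
                    degenerate = w$t == 0 & s1 == 0 & s2 == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$rank <- rank(res$p, ties.method = "first")
  attr(res, "groups") <- stats::setNames(c(n1, n2), levels(labels))
  class(res) <- c("ttest_result", "data.frame")
  res
}

#' Select significant features by the p < threshold rule
#'
#' Retains the columns whose two-sided Welch p-value is strictly below the
#' threshold, ordered by ascending p. No multiple-testing correction is
#' applied (a deliberate, documented caveat).
#'
#' @param result A [ttest_rank()] result (or any data.frame with `p`).
#' @param p_threshold Significance threshold (default 0.05).
#' @return Integer vector of column indices, named by feature, ordered by
#'   ascending p; may be empty.
#' @export
select_features <- function(result, p_threshold = 0.05) {
  if (!("p" %in% names(result))) stopf("`result` must contain a `p` column")
  keep <- which(result$p < p_threshold)
  keep <- keep[order(result$p[keep])]
  stats::setNames(keep, if ("feature" %in% names(result)) result$feature[keep])
}

#' The printed LSDA t-test summary table bundled with the package
#'
#' Group means/SDs, p- and t-values of the 30 LSDA components as reported
#' for a 37 + 40 subject EEG study; used by the regression checks and the
#' acceptance script as a fixed numeric input.
#'
#' @return data.frame with columns feature, mean_normal, sd_normal,
#'   mean_asd, sd_asd, p, t.
#' @export
lsda_ttest_table <- function() {
  path <- system.file("extdata", "lsda_ttest_table.csv", package = "bispeeg",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
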