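table2 <- lsda_ttest_table()

test_that("Welch t from summaries matches stats::t.test on raw vectors", {
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2))
    ref <- stats::t.test(x, y)
    got <- welch_t_from_summary(mean(x), sd(x), length(x),
                                mean(y), sd(y), length(y))
    expect_equal(got$t, abs(unname(ref$statistic)), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Welch t reproduces the published summary-table values", {
  w <- welch_t_from_summary(-1756.04, 1126.778, 37, -801.964, 1080.377, 40)
  expect_equal(w$t, 3.7863, tolerance = 1e-3)
  w2 <- welch_t_from_summary(-1402.45, 544.1245, 37, -2004.56, 909.222, 40)
  expect_equal(w2$t, 3.5560, tolerance = 1e-3)
})

test_that("degenerate summaries follow the stated conventions", {
  z <- welch_t_from_summary(1, 0, 5, 1, 0, 5)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  eq <- welch_t_from_summary(0, 1, 10, 0, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_t_from_summary(0, -1, 5, 0, 1, 5), ">= 0")
  expect_error(welch_t_from_summary(0, 1, 1, 0, 1, 5), ">= 2")
})

test_that("ttest_rank agrees bit-level with the summary route and ranks by p", {
  set.seed(42)
  Z <- matrix(rnorm(40 * 6), 40, 6)
  Z[1:20, 3] <- Z[1:20, 3] + 2
  y <- rep(c("a", "b"), each = 20)
  tt <- ttest_rank(Z, y)
  for (j in 1:6) {
    w <- welch_t_from_summary(mean(Z[1:20, j]), sd(Z[1:20, j]), 20,
                              mean(Z[21:40, j]), sd(Z[21:40, j]), 20)
    expect_identical(tt$t[j], w$t)
    expect_identical(tt$p[j], w$p)
  }
  expect_equal(tt$rank[order(tt$p)], 1:6)

  # a perfect separator gets the smallest p; duplicates tie exactly
  Z2 <- cbind(Z, sep = ifelse(y == "a", 0, 1) + rnorm(40, sd = 1e-3))
  tt2 <- ttest_rank(Z2, y)
  expect_equal(which.min(tt2$p), 7L)
  Z3 <- cbind(Z[, 1], Z[, 1])
  tt3 <- ttest_rank(Z3, y)
  expect_identical(tt3$t[1], tt3$t[2])

  # constant column in both classes is flagged, not an error
  Z4 <- cbind(Z[, 1], 3)
  tt4 <- ttest_rank(Z4, y)
  expect_true(tt4$degenerate[2])
  expect_equal(tt4$p[2], 1)
})

test_that("p-values are uniform under label permutation", {
  set.seed(43)
  Z <- matrix(rnorm(30), 30, 1)
  y0 <- rep(c("a", "b"), each = 15)
  ps <- replicate(200, ttest_rank(Z, sample(y0))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("selection keeps the published sub-threshold rows in ascending-p order", {
  sel <- select_features(table2, 0.05)
  expect_named(sel, c("LSDA13", "LSDA8", "LSDA9", "LSDA11", "LSDA7", "LSDA2"))
  expect_length(select_features(table2, 0), 0)
  all_sel <- select_features(table2, 1.1)
  expect_equal(sort(unname(all_sel)), seq_len(nrow(table2)))
  expect_equal(unname(all_sel), order(table2$p))
})

test_that("LSDA recovers the discriminative axis of separated clouds", {
  cl <- make_clouds()
  model <- lsda_fit(cl$X, cl$y, k = 5, alpha = 0.5, d = 2)
  a <- model$projection[, 1]
  cosine <- abs(a[1]) / sqrt(sum(a^2))
  expect_gt(cosine, 0.95)

  Z <- lsda_transform(model, cl$X)
  expect_equal(dim(Z), c(200, 2))
  expect_equal(colnames(Z), c("LSDA1", "LSDA2"))
})

test_that("LSDA handles 1-D input, rejects bad d, and requires two classes", {
  set.seed(44)
  x <- matrix(c(rnorm(10), rnorm(10, 5)), ncol = 1)
  y <- rep(c("a", "b"), each = 10)
  m <- lsda_fit(x, y, k = 3, d = 1)
  z <- lsda_transform(m, x)
  expect_equal(order(z), order(x * sign(m$projection[1, 1])))

  expect_error(lsda_fit(x, y, k = 3, d = 2), "exceeds")
  expect_error(lsda_fit(x, rep("a", 20), k = 3, d = 1), "two classes")
  expect_error(lsda_transform(m, matrix(0, 2, 3)), "features")
})

test_that("transform is affine-consistent and LSDA is feature-permutation invariant", {
  cl <- make_clouds(n1 = 30, n2 = 30, dims = 4, seed = 45)
  m <- lsda_fit(cl$X, cl$y, k = 4, d = 3)
  Z1 <- lsda_transform(m, cl$X)
  Z2 <- lsda_transform(m, cl$X + 2)   # constant shift of every feature
  shift <- Z2 - Z1
  expect_lt(max(abs(sweep(shift, 2L, shift[1, ]))), 1e-9)

  perm <- c(3, 1, 4, 2)
  mp <- lsda_fit(cl$X[, perm], cl$y, k = 4, d = 3)
  expect_equal(mp$eigenvalues, m$eigenvalues, tolerance = 1e-8)
})
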