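# The canonical worked example: two gray levels, all runs of length 2.
example_img <- matrix(c(0, 0, 1, 1,
                        0, 0, 1, 1), nrow = 2, byrow = TRUE)

test_that("glrlm counts maximal runs per direction on the worked example", {
  r0 <- glrlm(example_img, 0)
  expect_equal(r0$P[1, 2], 2L)   # level index 1 (pixel 0), length 2
  expect_equal(r0$P[2, 2], 2L)
  expect_equal(r0$n_runs, 4)
  expect_equal(sum(r0$P), 4L)

  r90 <- glrlm(example_img, 90)
  expect_equal(r90$P[1, 2], 2L)
  expect_equal(r90$P[2, 2], 2L)

  # 45-degree scan: the two anti-diagonals inside each level form one
  # 2-pixel run; the two crossing anti-diagonals split into 1-pixel runs
  r45 <- glrlm(example_img, 45)
  expect_equal(unname(r45$P[, 1]), c(2L, 2L))
  expect_equal(unname(r45$P[, 2]), c(1L, 1L))
  expect_equal(r45$n_runs, 6)

  expect_error(glrlm(matrix(c(0.5, 1), 1, 2), 0), "integers")
})

test_that("constant and checkerboard images give the closed-form features", {
  N <- 7
  const <- matrix(0L, 1, N)
  rc <- glrlm(const, 0)
  expect_equal(rc$P[1, N], 1L)
  expect_equal(rc$n_runs, 1)
  f <- run_length_features(rc)
  expect_equal(f[["SRE"]], 1 / N^2)
  expect_equal(f[["LRE"]], N^2)
  expect_equal(f[["RP"]], 1 / N)

  board <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  fb <- run_length_features(glrlm(board, 0))
  expect_equal(fb[["SRE"]], 1)
  expect_equal(fb[["LRE"]], 1)
  expect_equal(fb[["RP"]], 1)
})

test_that("run-length features on the worked example match hand-computed values", {
  f <- run_length_features(glrlm(example_img, 0))
  expect_equal(f[["SRE"]], 0.25)
  expect_equal(f[["LRE"]], 4)
  expect_equal(f[["RP"]], 0.5)
  expect_equal(f[["GLN"]], 2)
  expect_equal(f[["RLN"]], 4)
  expect_equal(f[["LGRE"]], 0.625)
  expect_equal(f[["HGRE"]], 2.5)
  expect_equal(f[["SRLGE"]], 0.625 / 4)
  expect_equal(f[["LRHGE"]], 40 / 4)
})

test_that("glrlm agrees exactly with a per-pixel run scanner on random images", {
  set.seed(31)
  for (rep in 1:100) {
    nr <- sample(2:16, 1); nc <- sample(2:16, 1)
    G <- sample(2:5, 1)
    img <- matrix(sample(0:(G - 1), nr * nc, replace = TRUE), nr, nc)
    for (dir in c(0, 45, 90, 135)) {
      got <- glrlm(img, dir, n_levels = G)
      want <- oracle_rlm(img, dir, G, max(nr, nc))
      expect_identical(unname(got$P), want)
      # tiling: every pixel in exactly one run
      expect_equal(sum(sweep(got$P, 2L, seq_len(ncol(got$P)), `*`)), nr * nc)
    }
  }
})

test_that("SRE <= 1 <= LRE with equality iff all runs have length one", {
  set.seed(32)
  for (rep in 1:20) {
    img <- matrix(sample(0:2, 48, replace = TRUE), 6, 8)
    f <- run_length_features(glrlm(img, 0))
    expect_lte(f[["SRE"]], 1)
    expect_gte(f[["LRE"]], 1)
  }
})

test_that("entropy measures reproduce closed forms on degenerate and uniform histograms", {
  # uniform over 4 of 4 levels: one pixel per level
  img4 <- matrix(0:3, 1, 4)
  e4 <- entropy_features(img4)
  expect_equal(e4[["shannon_entropy"]], 2)
  expect_equal(e4[["renyi_entropy"]], 2)      # alpha = 2, uniform: log2 N
  expect_equal(e4[["vajda_entropy"]], 1 - 1 / 4)

  # degenerate: single level occupied
  imgd <- matrix(0L, 2, 2)
  ed <- entropy_features(imgd, n_levels = 4)
  expect_equal(ed[["shannon_entropy"]], 0)
  expect_equal(ed[["vajda_entropy"]], 0)
  expect_equal(ed[["max_entropy"]], 0)

  expect_error(entropy_features(imgd, n_levels = 1), "at least 2")
})

test_that("entropy bounds and Renyi monotonicity hold on random images", {
  set.seed(33)
  for (rep in 1:20) {
    G <- sample(c(4, 8, 16), 1)
    img <- matrix(sample(0:(G - 1), 200, replace = TRUE,
                         prob = runif(G)), 10, 20)
    e <- entropy_features(img, n_levels = G)
    expect_gte(e[["shannon_entropy"]], 0)
    expect_lte(e[["shannon_entropy"]], log2(G) + 1e-12)
    expect_lte(e[["renyi_entropy"]], e[["shannon_entropy"]] + 1e-12)
  }
})

test_that("the 18-feature vector is named, finite, and symmetric under transpose", {
  set.seed(34)
  img <- matrix(sample(0:7, 15 * 11, replace = TRUE), 15, 11)
  f <- extract_features(img)
  expect_named(f, bispeeg_feature_names)
  expect_true(all(is.finite(f)))
  # the direction set {0,45,90,135} is transpose-closed
  expect_equal(extract_features(t(img)), f)
})

test_that("gray-level complement leaves level-agnostic run features unchanged", {
  set.seed(35)
  img <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
  comp <- 7L - img
  f1 <- extract_features(img)
  f2 <- extract_features(comp)
  for (nm in c("SRE", "LRE", "RP", "RLN"))
    expect_equal(f2[[nm]], f1[[nm]])
})
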