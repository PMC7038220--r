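# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: DFTs are computed by explicit matrix products,
# runs by a per-pixel scanner.

# Naive DFT (no FFT): O(n^2) matrix product.
naive_dft <- function(x, nfft = length(x)) {
  x <- c(x, rep(0, nfft - length(x)))
  k <- 0:(nfft - 1)
  W <- exp(-2i * pi * outer(k, k) / nfft)
  as.vector(W %*% x)
}

# Direct triple-product bispectrum oracle on the same blocks/taper the
# estimator uses, but with the naive DFT and explicit per-bin loops.
oracle_bispectrum <- function(x, block_len, nfft, overlap_frac, window = "hann") {
  step <- max(1, round(block_len * (1 - overlap_frac)))
  starts <- seq(1, length(x) - block_len + 1, by = step)
  taper <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * (0:(block_len - 1)) / (block_len - 1))
  else rep(1, block_len)
  h <- nfft / 2
  acc <- matrix(0 + 0i, h + 1, h + 1)
  for (s in starts) {
    blk <- x[s:(s + block_len - 1)]
    blk <- (blk - mean(blk)) * taper
    X <- naive_dft(blk, nfft)
    for (k1 in 0:h) for (k2 in 0:h) {
      k3 <- (k1 + k2) %% nfft
      acc[k1 + 1, k2 + 1] <- acc[k1 + 1, k2 + 1] +
        X[k1 + 1] * X[k2 + 1] * Conj(X[k3 + 1])
    }
  }
  acc / length(starts)
}

# Per-pixel run scanner: walks every scan line of a direction pixel by
# pixel, emitting (level, length) pairs of maximal runs.
oracle_runs <- function(img, direction) {
  nr <- nrow(img); nc <- ncol(img)
  lines <- switch(as.character(direction),
    "0"   = lapply(seq_len(nr), function(i) img[i, ]),
    "90"  = lapply(seq_len(nc), function(j) img[, j]),
    "45"  = lapply(2:(nr + nc), function(s) {
      i <- seq_len(nr); j <- s - i
      ok <- j >= 1 & j <= nc
      img[cbind(i[ok], j[ok])]
    }),
    "135" = lapply((1 - nc):(nr - 1), function(dd) {
      i <- seq_len(nr); j <- i - dd
      ok <- j >= 1 & j <= nc
      img[cbind(i[ok], j[ok])]
    }))
  out <- list()
  for (ln in lines) {
    ln <- ln[!is.na(ln)]
    if (!length(ln)) next
    start <- 1
    for (pos in seq_along(ln)) {
      if (pos == length(ln) || ln[pos + 1] != ln[pos]) {
        out[[length(out) + 1]] <- c(level = ln[start], len = pos - start + 1)
        start <- pos + 1
      }
    }
  }
  do.call(rbind, out)
}

# Rebuild a G x R count matrix from oracle_runs output.
oracle_rlm <- function(img, direction, G, rmax) {
  runs <- oracle_runs(img, direction)
  P <- matrix(0L, G, rmax)
  if (!is.null(runs))
    for (r in seq_len(nrow(runs)))
      P[runs[r, 1] + 1L, runs[r, 2]] <- P[runs[r, 1] + 1L, runs[r, 2]] + 1L
  P
}

# Two well-separated Gaussian clouds differing only along the first axis.
make_clouds <- function(n1 = 100, n2 = 100, dims = 5, sep = 6, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * dims), n1),
             matrix(rnorm(n2 * dims), n2))
  X[(n1 + 1):(n1 + n2), 1] <- X[(n1 + 1):(n1 + n2), 1] + sep
  list(X = X, y = factor(rep(c("a", "b"), c(n1, n2))))
}

# Small, fast synthetic cohort for pipeline-level tests.
tiny_synth_config <- function(seed, coupling_normal = 0.1, coupling_asd = 0.9,
                              n_per_class = 10) {
  synth_config(n_normal = n_per_class, n_asd = n_per_class, n_channels = 2,
               duration_s = 12, coupling_normal = coupling_normal,
               coupling_asd = coupling_asd, seed = seed)
}
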