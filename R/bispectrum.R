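#' Bispectrum estimation parameters
#'
#' Defaults give roughly 20 averaged blocks from a 5519-sample segment
#' (block 512, 50% overlap), a reasonable bias/variance compromise for
#' texture-feature stability.
#'
#' @param nfft FFT length (even; >= block_len).
#' @param block_len Samples per block.
#' @param block_overlap Fractional overlap between consecutive blocks.
#' @param window Block taper: "hann" or "rect".
#' @param use_principal_domain If TRUE, downstream images restrict to the
#'   non-redundant triangle 0 <= f2 <= f1, f1 + f2 <= fs/2; by default the
#'   full symmetric half-grid f1, f2 in [0, fs/2] is used.
#' @return A `bispectrum_config` list.
#' @export
bispectrum_config <- function(nfft = 512L, block_len = 512L,
                              block_overlap = 0.5, window = c("hann", "rect"),
                              use_principal_domain = FALSE) {
  nfft <- assert_count(nfft, "nfft", min = 4L)
  block_len <- assert_count(block_len, "block_len", min = 4L)
  if (nfft %% 2L != 0L) stopf("`nfft` must be even")
  if (nfft < block_len) stopf("`nfft` must be >= `block_len`")
  structure(list(nfft = nfft, block_len = block_len,
                 block_overlap = assert_number(block_overlap, "block_overlap", 0, 0.95),
                 window = match.arg(window),
                 use_principal_domain = isTRUE(use_principal_domain)),
            class = "bispectrum_config")
}

#' Direct (FFT, block-averaged) bispectrum estimate of a segment
#'
#' The segment is cut into K overlapping blocks; each block is mean-removed,
#' tapered, and FFT'd; the estimate averages the triple products
#' X(f1) X(f2) conj(X(f1 + f2)) over blocks on the bifrequency grid
#' f1, f2 in [0, fs/2]. Quadratic phase coupling at (f1, f2) makes the
#' summands phase-align across blocks and so survive averaging, while
#' incidental (random-phase) energy cancels; for Gaussian input the
#' bispectrum converges to zero.
#'
#' @param segment An [eeg_segment()] or numeric vector.
#' @param config A [bispectrum_config()].
#' @param fs Sampling rate; taken from the segment when available.
#' @return `bispectrum_matrix`: complex `values` on the (nfft/2+1)^2 grid,
#'   `freq_axis` in Hz, `n_blocks_averaged`, and the config.
#' @export
estimate_bispectrum <- function(segment, config = bispectrum_config(),
                                fs = NULL) {
  if (inherits(segment, "eeg_segment")) {
    fs <- fs %||% segment$fs
    x <- segment$samples
  } else {
    x <- as.numeric(segment)
  }
  if (is.null(fs)) stopf("supply `fs` for plain numeric segments")
  if (anyNA(x) || any(!is.finite(x))) stopf("segment contains non-finite samples")
  n <- length(x)
  if (n < config$block_len)
    stopf("segment length %d < block length %d", n, config$block_len)
  step <- max(1L, as.integer(round(config$block_len * (1 - config$block_overlap))))
  starts <- seq.int(1L, n - config$block_len + 1L, by = step)
  K <- length(starts)
  taper <- switch(config$window,
                  hann = 0.5 - 0.5 * cos(2 * pi * seq.int(0L, config$block_len - 1L) /
                                           (config$block_len - 1L)),
                  rect = rep(1, config$block_len))
  h <- config$nfft %/% 2L
  half <- seq_len(h + 1L)
  # index of bin f1+f2 in the full-length FFT, with wrap-around at nfft (=fs)
  sum_idx <- (outer(0:h, 0:h, `+`) %% config$nfft) + 1L
  acc <- matrix(0 + 0i, h + 1L, h + 1L)
  for (s in starts) {
    blk <- x[s:(s + config$block_len - 1L)]
    blk <- (blk - mean(blk)) * taper
    X <- stats::fft(c(blk, rep(0, config$nfft - config$block_len)))
    Xh <- X[half]
    Xs <- Conj(X[sum_idx])
    dim(Xs) <- c(h + 1L, h + 1L)
    acc <- acc + tcrossprod(Xh) * Xs
  }
  structure(list(values = acc / K,
                 freq_axis = (0:h) * fs / config$nfft,
                 fs = fs, n_blocks_averaged = K, config = config),
            class = "bispectrum_matrix")
}

#' @export
print.bispectrum_matrix <- function(x, ...) {
  cat(sprintf("Bispectrum estimate: %dx%d grid, 0-%g Hz, %d blocks averaged\n",
              nrow(x$values), ncol(x$values), max(x$freq_axis),
              x$n_blocks_averaged))
  invisible(x)
}

#' Principal-domain mask of the bispectrum
#'
#' The bispectrum of a real signal is fully determined by its values on the
#' triangle 0 <= f2 <= f1, f1 + f2 <= fs/2. Returns the logical mask of that
#' region on the half-grid used by [estimate_bispectrum()]; entry (i, j)
#' refers to frequency bins (i-1, j-1).
#'
#' @param nfft FFT length (even).
#' @param fs Sampling rate (only used to attach the frequency axis).
#' @return Logical (nfft/2+1)^2 matrix with attribute `freq_axis`.
#' @export
principal_domain_mask <- function(nfft, fs = 1) {
  nfft <- assert_count(nfft, "nfft", min = 4L)
  if (nfft %% 2L != 0L) stopf("`nfft` must be even")
  h <- nfft %/% 2L
  b1 <- outer(0:h, 0:h, function(i, j) i)
  b2 <- outer(0:h, 0:h, function(i, j) j)
  mask <- (b2 <= b1) & (b1 + b2 <= h)
  attr(mask, "freq_axis") <- (0:h) * fs / nfft
  mask
}

#' Quantize a bispectrum magnitude into a gray-level image
#'
#' Applies the chosen magnitude scaling (log1p compresses the heavy dynamic
#' range typical of bispectra), then min-max quantizes onto G gray levels:
#' `pixel = floor(G * (m - min) / (max - min))` clamped to G-1. A constant
#' magnitude maps to all-zero pixels. The quantization makes the image
#' invariant to overall amplitude scaling of the input signal.
#'
#' @param B A `bispectrum_matrix` (or numeric magnitude matrix).
#' @param G Number of gray levels (default 64).
#' @param scaling "log1p" or "linear".
#' @param mask Optional logical matrix; pixels outside it become NA and are
#'   excluded from texture statistics (used with [principal_domain_mask()]).
#' @return `gray_image`: integer `pixels` in 0..G-1 (NA outside mask),
#'   `n_gray_levels`, `scaling`.
#' @export
magnitude_image <- function(B, G = 64L, scaling = c("log1p", "linear"),
                            mask = NULL) {
  scaling <- match.arg(scaling)
  G <- assert_count(G, "G", min = 2L)
  m <- if (inherits(B, "bispectrum_matrix")) Mod(B$values) else abs(B)
  if (!is.null(mask)) m[!mask] <- NA
  if (all(is.na(m))) stopf("no finite magnitudes to quantize")
  m <- switch(scaling, log1p = log1p(m), linear = m)
  lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
  pix <- if (hi > lo) pmin(floor(G * (m - lo) / (hi - lo)), G - 1L)
         else m * 0
  storage.mode(pix) <- "integer"
  structure(list(pixels = pix, n_gray_levels = G, scaling = scaling),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("Gray image %dx%d, %d levels (%s scaling)\n",
              nrow(x$pixels), ncol(x$pixels), x$n_gray_levels, x$scaling))
  invisible(x)
}
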