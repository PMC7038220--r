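#' Names of the 18 texture features, in canonical order
#'
#' Seven histogram entropy/energy measures followed by eleven gray-level
#' run-length features.
#' @export
bispeeg_feature_names <- c(
  "log_energy", "kapur_entropy", "max_entropy", "renyi_entropy",
  "shannon_entropy", "vajda_entropy", "yager_entropy",
  "SRE", "LRE", "GLN", "RLN", "RP",
  "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")

#' Entropy-measure parameters
#'
#' @param renyi_alpha Renyi order (> 0, != 1; default 2).
#' @param kapur_alpha,kapur_beta Orders of the two-parameter Kapur entropy.
#' @param epsilon Additive guard inside the log-energy logarithm.
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(renyi_alpha = 2, kapur_alpha = 0.5,
                           kapur_beta = 0.7, epsilon = 1e-12) {
  if (renyi_alpha <= 0 || renyi_alpha == 1)
    stopf("`renyi_alpha` must be > 0 and != 1")
  if (kapur_alpha == kapur_beta) stopf("`kapur_alpha` must differ from `kapur_beta`")
  structure(list(renyi_alpha = renyi_alpha, kapur_alpha = kapur_alpha,
                 kapur_beta = kapur_beta,
                 epsilon = assert_number(epsilon, "epsilon", lo = 0)),
            class = "entropy_config")
}

image_pixels <- function(image) {
  if (inherits(image, "gray_image")) return(image)
  if (!is.matrix(image)) stopf("`image` must be a matrix or gray_image")
  if (any(image != round(image), na.rm = TRUE))
    stopf("image gray levels must be integers")
  vals <- image[!is.na(image)]
  if (!length(vals)) stopf("image is empty")
  if (min(vals) < 0) stopf("image gray levels must be >= 0")
  storage.mode(image) <- "integer"
  structure(list(pixels = image, n_gray_levels = max(vals) + 1L,
                 scaling = "linear"), class = "gray_image")
}

#' Gray-level run-length matrix of an image in one direction
#'
#' Counts maximal runs of equal gray level along 0 (rows), 45
#' (anti-diagonals), 90 (columns) or 135 (main diagonals) degrees. Every
#' non-NA pixel belongs to exactly one run per direction, so
#' `sum(j * P[i, j]) == n_pixels`. Gray levels are 0-based in the image and
#' indexed 1..G in `P` (level g occupies row g + 1).
#'
#' @param image Integer matrix (levels 0..G-1, NA allowed for masked pixels)
#'   or `gray_image`.
#' @param direction One of 0, 45, 90, 135.
#' @param n_levels Number of gray levels G; defaults to the image's.
#' @return `rlm`: counts `P` (G x Rmax), `direction`, `n_runs`, `n_pixels`.
#' @export
glrlm <- function(image, direction = 0, n_levels = NULL) {
  img <- image_pixels(image)
  if (!direction %in% c(0, 45, 90, 135)) stopf("direction must be 0, 45, 90 or 135")
  G <- as.integer(n_levels %||% img$n_gray_levels)
  px <- img$pixels
  if (any(px >= G, na.rm = TRUE)) stopf("gray level >= n_levels found")
  nr <- nrow(px); nc <- ncol(px)
  # Serialize the direction's scan lines into one vector with a -1 separator
  # between lines (and at NAs), so a single rle() call finds all runs.
  lines <- switch(as.character(direction),
    "0"   = split(px, row(px)),
    "90"  = split(px, col(px)),
    "45"  = split(px, row(px) + col(px)),
    "135" = split(px, row(px) - col(px)))
  v <- unlist(lapply(lines, function(l) c(l, -1L)), use.names = FALSE)
  v[is.na(v)] <- -1L
  r <- rle(v)
  keep <- r$values >= 0L
  vals <- r$values[keep] + 1L          # 1-based level index
  lens <- r$lengths[keep]
  n_pixels <- sum(!is.na(px))
  rmax <- max(nr, nc)
  P <- matrix(0L, nrow = G, ncol = rmax,
              dimnames = list(level = NULL, run_length = NULL))
  if (length(vals))
    P[] <- tabulate((lens - 1L) * G + vals, nbins = G * rmax)
  structure(list(P = P, direction = direction, n_runs = length(lens),
                 n_pixels = n_pixels),
            class = "rlm")
}

rlm_features_one <- function(rlm) {
  P <- rlm$P
  n_r <- sum(P)
  if (n_r == 0) stopf("run-length matrix has no runs")
  i2 <- seq_len(nrow(P))^2
  j2 <- seq_len(ncol(P))^2
  gl_sum <- rowSums(P)       # runs per gray level
  rl_sum <- colSums(P)       # runs per length
  wj <- function(w) sweep(P, 2L, w, `*`)
  c(SRE   = sum(wj(1 / j2)) / n_r,
    LRE   = sum(wj(j2)) / n_r,
    GLN   = sum(gl_sum^2) / n_r,
    RLN   = sum(rl_sum^2) / n_r,
    RP    = n_r / rlm$n_pixels,
    LGRE  = sum(P / i2) / n_r,
    HGRE  = sum(P * i2) / n_r,
    SRLGE = sum(wj(1 / j2) / i2) / n_r,
    SRHGE = sum(wj(1 / j2) * i2) / n_r,
    LRLGE = sum(wj(j2) / i2) / n_r,
    LRHGE = sum(wj(j2) * i2) / n_r)
}

#' Eleven run-length features, averaged over directions
#'
#' With 1-based gray level i and run length j, and n_r runs over n_p pixels:
#' SRE = (1/n_r) sum P/j^2, LRE = (1/n_r) sum P j^2,
#' GLN = (1/n_r) sum_i (sum_j P)^2, RLN = (1/n_r) sum_j (sum_i P)^2,
#' RP = n_r/n_p, LGRE/HGRE weight by 1/i^2 and i^2, and the four joint
#' emphases combine the i and j weights. Each feature is computed per
#' direction with that direction's own n_r, then averaged.
#'
#' @param rlms A single `rlm` or a list of them (typically the 4 directions).
#' @return Named numeric vector of the 11 features.
#' @export
run_length_features <- function(rlms) {
  if (inherits(rlms, "rlm")) rlms <- list(rlms)
  stopifnot(all(vapply(rlms, inherits, logical(1), "rlm")))
  rowMeans(vapply(rlms, rlm_features_one, numeric(11)))
}

#' Seven entropy and energy measures of the gray-level histogram
#'
#' Let p be the G-bin gray-level histogram of the (quantized) image,
#' normalized to sum 1. Then: shannon = -sum p log2 p (zero bins skipped);
#' renyi = log2(sum p^alpha)/(1-alpha); kapur = log2(sum p^a / sum p^b)/(b-a);
#' max_entropy = -log2 max p (the min-entropy); vajda = sum p(1-p) (quadratic
#' entropy); yager = 1 - sum|2p-1|/G (a fuzziness-style measure); log_energy
#' = sum log2(p^2 + eps), with eps guarding empty bins.
#'
#' @param image Integer matrix or `gray_image`.
#' @param config An [entropy_config()].
#' @param n_levels Histogram bin count G; defaults to the image's gray levels.
#' @return Named numeric vector of the 7 measures.
#' @export
entropy_features <- function(image, config = entropy_config(),
                             n_levels = NULL) {
  img <- image_pixels(image)
  G <- as.integer(n_levels %||% img$n_gray_levels)
  if (G < 2L) stopf("need at least 2 gray levels")
  vals <- img$pixels[!is.na(img$pixels)]
  p <- tabulate(vals + 1L, nbins = G) / length(vals)
  pp <- p[p > 0]
  a <- config$renyi_alpha
  c(log_energy = sum(log2(p^2 + config$epsilon)),
    kapur_entropy = log2(sum(pp^config$kapur_alpha) / sum(pp^config$kapur_beta)) /
      (config$kapur_beta - config$kapur_alpha),
    max_entropy = -log2(max(p)),
    renyi_entropy = log2(sum(pp^a)) / (1 - a),
    shannon_entropy = -sum(pp * log2(pp)),
    vajda_entropy = sum(p * (1 - p)),
    yager_entropy = 1 - sum(abs(2 * p - 1)) / G)
}

#' The full 18-feature texture vector of a bispectrum gray image
#'
#' Entropy measures on the gray-level histogram followed by run-length
#' features averaged over the four directions (0, 45, 90, 135 degrees); see
#' [entropy_features()] and [run_length_features()]. Feature order is
#' [bispeeg_feature_names].
#'
#' @param image A `gray_image` (or integer matrix).
#' @param config An [entropy_config()].
#' @return Named numeric vector of length 18.
#' @export
extract_features <- function(image, config = entropy_config()) {
  img <- image_pixels(image)
  ent <- entropy_features(img, config)
  rlms <- lapply(c(0, 45, 90, 135), function(d)
    glrlm(img, direction = d, n_levels = img$n_gray_levels))
  out <- c(ent, run_length_features(rlms))
  names(out) <- bispeeg_feature_names
  out
}
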