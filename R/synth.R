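#' Configuration for the synthetic QPC cohort generator
#'
#' Defines a two-class cohort of multichannel resting-style EEG whose classes
#' differ only in the prevalence of quadratic phase coupling (QPC) among
#' oscillatory triplets. Each triplet contributes cosines at f1, f2 and
#' f1 + f2; in a coupled triplet the third phase is the sum of the first two,
#' so the triplet lights up the bispectrum at bifrequency (f1, f2) while
#' leaving the power spectrum unchanged. Class contrast is therefore encoded
#' purely in phase structure, which is exactly what the bispectrum stage is
#' meant to detect.
#'
#' @param n_normal,n_asd Number of subjects per class.
#' @param n_channels Channels per recording.
#' @param fs Sampling frequency in Hz.
#' @param duration_s Recording duration per subject, seconds.
#' @param triplet_freqs List of c(f1, f2) pairs in Hz; each must satisfy
#'   f1 + f2 < fs/2 (and should sit inside the analysis band if the cohort is
#'   to be band-pass filtered downstream).
#' @param coupling_normal,coupling_asd Probability, per channel and triplet,
#'   that the triplet is phase-coupled, for each class.
#' @param noise_exponent Spectral slope gamma of the 1/f^gamma background.
#' @param snr_db Signal-to-noise ratio in dB (Inf disables noise).
#' @param phase_epoch_s Interval, in seconds, at which oscillator phases are
#'   re-drawn. Uncoupled triplets only cancel in block-averaged bispectra if
#'   their phases decorrelate within a segment, so this must be comparable to
#'   (or shorter than) the estimator's block length.
#' @param seed Integer RNG seed; identical seed and config give a
#'   bit-identical cohort.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_normal = 37L, n_asd = 40L, n_channels = 8L,
                         fs = 500, duration_s = 60,
                         triplet_freqs = list(c(8, 14), c(11, 17)),
                         coupling_normal = 0.1, coupling_asd = 0.9,
                         noise_exponent = 1, snr_db = 6,
                         phase_epoch_s = 0.5, seed = 1L) {
  cfg <- list(
    n_normal = assert_count(n_normal, "n_normal"),
    n_asd = assert_count(n_asd, "n_asd"),
    n_channels = assert_count(n_channels, "n_channels"),
    fs = assert_number(fs, "fs", lo = 1e-6),
    duration_s = assert_number(duration_s, "duration_s", lo = 1e-6),
    triplet_freqs = triplet_freqs,
    coupling_normal = assert_number(coupling_normal, "coupling_normal", 0, 1),
    coupling_asd = assert_number(coupling_asd, "coupling_asd", 0, 1),
    noise_exponent = assert_number(noise_exponent, "noise_exponent", 0),
    snr_db = snr_db,
    phase_epoch_s = assert_number(phase_epoch_s, "phase_epoch_s", 1e-6),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (!is.list(triplet_freqs) || !length(triplet_freqs) ||
      !all(vapply(triplet_freqs, function(p) is.numeric(p) && length(p) == 2L &&
                    all(p > 0), logical(1))))
    stopf("`triplet_freqs` must be a nonempty list of positive (f1, f2) pairs")
  sums <- vapply(triplet_freqs, sum, numeric(1))
  if (any(sums >= cfg$fs / 2))
    stopf("aliasing: triplet sum frequency %.6g Hz is >= fs/2 = %.6g Hz",
          max(sums), cfg$fs / 2)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic QPC cohort config: %d normal + %d ASD subjects, %d ch, %g Hz, %g s\n",
    x$n_normal, x$n_asd, x$n_channels, x$fs, x$duration_s))
  cat(sprintf("  coupling: normal %.2f vs asd %.2f; snr %s dB; 1/f^%g noise\n",
              x$coupling_normal, x$coupling_asd, format(x$snr_db),
              x$noise_exponent))
  invisible(x)
}

#' 1/f^gamma Gaussian background noise
#'
#' Shapes white Gaussian noise in the frequency domain so that power falls as
#' f^-gamma, the canonical broadband background of resting EEG. DC is zeroed,
#' output is scaled to unit variance.
#'
#' @param n Number of samples.
#' @param gamma Spectral exponent (0 gives white noise).
#' @return Numeric vector of length `n` with mean ~0 and variance 1.
#' @export
pink_noise <- function(n, gamma = 1) {
  n <- assert_count(n, "n", min = 2L)
  w <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # two-sided frequency index, hermitian-safe
  scale <- c(0, f[-1]^(-gamma / 2))
  x <- Re(stats::fft(w * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Generate one synthetic EEG channel with controllable phase coupling
#'
#' Builds a sum of cosine triplets at (f1, f2, f1+f2). Phases are re-drawn
#' every `phase_epoch_s` seconds; within each epoch a coupled triplet obeys
#' phi3 = phi1 + phi2 while an uncoupled one draws phi3 independently, so the
#' two cases have identical power spectra but differ in the bispectrum at
#' (f1, f2). Optional 1/f^gamma noise is added at the requested SNR and the
#' result is returned zero-mean.
#'
#' @param triplet_freqs List of c(f1, f2) pairs in Hz.
#' @param coupled Logical scalar or vector (one flag per triplet).
#' @param n_samples Length of the output signal.
#' @param fs Sampling frequency, Hz.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for a noiseless signal.
#' @param noise_exponent 1/f^gamma slope of the additive background.
#' @param phase_epoch_s Phase re-randomization interval, seconds.
#' @param amplitude Cosine amplitude (common to all components).
#' @param seed Optional seed; when given the segment is reproducible.
#' @return Numeric vector of length `n_samples`, zero mean.
#' @export
generate_qpc_segment <- function(triplet_freqs, coupled, n_samples, fs = 500,
                                 snr_db = Inf, noise_exponent = 1,
                                 phase_epoch_s = 0.5, amplitude = 1,
                                 seed = NULL) {
  if (!is.list(triplet_freqs)) triplet_freqs <- list(triplet_freqs)
  n_samples <- assert_count(n_samples, "n_samples", min = 8L)
  fs <- assert_number(fs, "fs", lo = 1e-6)
  sums <- vapply(triplet_freqs, sum, numeric(1))
  if (any(sums >= fs / 2))
    stopf("aliasing: f1 + f2 = %.6g Hz is >= fs/2 = %.6g Hz; choose lower triplet frequencies",
          max(sums), fs / 2)
  fres <- fs / n_samples
  if (any(unlist(triplet_freqs) < fres))
    stopf("triplet frequency below the resolution fs/n_samples = %.4g Hz", fres)
  coupled <- rep_len(as.logical(coupled), length(triplet_freqs))
  if (!is.null(seed)) set.seed(seed)

  t <- (seq_len(n_samples) - 1L) / fs
  epoch_len <- max(1L, round(phase_epoch_s * fs))
  starts <- seq.int(1L, n_samples, by = epoch_len)
  x <- numeric(n_samples)
  for (ti in seq_along(triplet_freqs)) {
    f1 <- triplet_freqs[[ti]][1]; f2 <- triplet_freqs[[ti]][2]
    for (s in starts) {
      idx <- s:min(s + epoch_len - 1L, n_samples)
      ph1 <- stats::runif(1, 0, 2 * pi)
      ph2 <- stats::runif(1, 0, 2 * pi)
      ph3 <- if (coupled[ti]) ph1 + ph2 else stats::runif(1, 0, 2 * pi)
      tt <- t[idx]
      x[idx] <- x[idx] + amplitude * (
        cos(2 * pi * f1 * tt + ph1) +
        cos(2 * pi * f2 * tt + ph2) +
        cos(2 * pi * (f1 + f2) * tt + ph3))
    }
  }
  if (is.finite(snr_db)) {
    noise <- pink_noise(n_samples, gamma = noise_exponent)
    noise_sd <- stats::sd(x) / 10^(snr_db / 20)
    x <- x + noise * noise_sd
  }
  x - mean(x)
}

#' Generate a labeled two-class synthetic EEG cohort
#'
#' One [eeg_record] per subject. Each class uses its own coupling probability
#' (`coupling_normal`, `coupling_asd`): for every channel and triplet a
#' Bernoulli draw decides whether the triplet is phase-coupled in that
#' channel. Per-subject triplet frequencies are jittered by up to 1 Hz to
#' create inter-subject variability.
#'
#' @param config A [synth_config()].
#' @return List of `eeg_record` objects, `n_normal + n_asd` long, with
#'   `class_label` "normal" or "asd". Each record carries a `coupled`
#'   channels-x-triplets logical matrix recording the ground-truth coupling
#'   draws, for provenance and debugging.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_samples <- round(config$duration_s * config$fs)
  classes <- c(rep("normal", config$n_normal), rep("asd", config$n_asd))
  p_class <- c(normal = config$coupling_normal, asd = config$coupling_asd)
  lapply(seq_along(classes), function(i) {
    cls <- classes[i]
    freqs <- lapply(config$triplet_freqs, function(p) {
      pmax(p + stats::runif(2, -1, 1), config$fs / n_samples * 2)
    })
    data <- matrix(0, nrow = config$n_channels, ncol = n_samples)
    coupled <- matrix(FALSE, config$n_channels, length(freqs))
    for (ch in seq_len(config$n_channels)) {
      coupled[ch, ] <- stats::runif(length(freqs)) < p_class[[cls]]
      data[ch, ] <- generate_qpc_segment(
        freqs, coupled[ch, ], n_samples, fs = config$fs,
        snr_db = config$snr_db, noise_exponent = config$noise_exponent,
        phase_epoch_s = config$phase_epoch_s)
    }
    rec <- eeg_record(data, fs = config$fs,
                      channel_names = sprintf("ch%02d", seq_len(config$n_channels)),
                      subject_id = sprintf("S%03d", i),
                      class_label = cls)
    rec$coupled <- coupled   # ground-truth provenance, channels x triplets
    rec
  })
}

#' Write a cohort to disk as per-subject files plus a label manifest
#'
#' @param cohort List of `eeg_record` (e.g. from [generate_cohort()]).
#' @param dir Output directory, created if needed.
#' @param format "csv" (one column per channel, header = channel names) or
#'   "edf" (16-bit EDF, see [write_edf()]).
#' @return Invisibly, the manifest data frame (subject_id, class, file).
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    files[i] <- file.path(dir, paste0(rec$subject_id, ".", format))
    if (format == "csv") {
      df <- as.data.frame(t(rec$data))
      names(df) <- rec$channel_names
      utils::write.csv(df, files[i], row.names = FALSE)
    } else {
      write_edf(rec, files[i])
    }
  }
  manifest <- data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, character(1)),
    class = vapply(cohort, function(r) r$class_label, character(1)),
    file = basename(files),
    fs = vapply(cohort, function(r) r$fs, numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and per-subject files.
#' @return List of `eeg_record`.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stopf("no manifest.csv in %s", dir)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    rec <- read_recording(file.path(dir, mf$file[i]),
                          fs = if ("fs" %in% names(mf)) mf$fs[i] else NULL)
    rec$subject_id <- mf$subject_id[i]
    rec$class_label <- mf$class[i]
    rec
  })
}
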