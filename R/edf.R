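# Minimal EDF (European Data Format) support: 16-bit samples, one data
# record spanning the whole signal, identical length and rate across
# channels. Enough to interchange the cohorts this package generates;
# not a general-purpose EDF implementation (no annotations, no EDF+).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG record as a 16-bit EDF file
#'
#' Samples are linearly quantized to the signed 16-bit digital range over
#' each channel's physical min/max, so amplitudes round-trip only to about
#' 1/65000 of the channel range.
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  ns <- nrow(record$data)
  n <- ncol(record$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(record$subject_id, 80),
    edf_pad("bispeeg synthetic", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(1L, 8),                              # one data record
    edf_pad(format(n / record$fs, digits = 7), 8),
    edf_pad(ns, 4)), con, eos = NULL)
  phys_min <- apply(record$data, 1L, min)
  phys_max <- apply(record$data, 1L, max)
  flat <- phys_max <= phys_min
  phys_max[flat] <- phys_min[flat] + 1
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  writeChar(paste0(
    field(record$channel_names, 16),
    field(rep("", ns), 80),                      # transducer
    field(rep("uV", ns), 8),
    field(formatC(phys_min, digits = 7, width = 8), 8),
    field(formatC(phys_max, digits = 7, width = 8), 8),
    field(rep(-32768L, ns), 8),
    field(rep(32767L, ns), 8),
    field(rep("", ns), 80),                      # prefiltering
    field(rep(n, ns), 8),
    field(rep("", ns), 32)), con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((record$data[ch, ] - phys_min[ch]) /
                   (phys_max[ch] - phys_min[ch]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file written by [write_edf()]
#'
#' Handles continuous EDF with equal per-signal rates; multi-record files are
#' concatenated in time.
#'
#' @param path EDF file path.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                          # version
  subject <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L)
    stopf("EDF with per-signal sampling rates is not supported")
  out <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  for (rec in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      cols <- ((rec - 1L) * spr[ch] + 1L):(rec * spr[ch])
      out[ch, cols] <- phys_min[ch] + (dig - dig_min[ch]) /
        (dig_max[ch] - dig_min[ch]) * (phys_max[ch] - phys_min[ch])
    }
  }
  eeg_record(out, fs = spr[1] / dur, channel_names = labels,
             subject_id = subject)
}
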