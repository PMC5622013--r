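# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# one-second data records, physical units microvolts. Covers exactly what the
# fixture round trip needs; not a general-purpose EDF implementation.

pad_field <- function(x, width) {
  x <- substr(format(x, trim = TRUE), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a channels-by-samples matrix as EDF
#'
#' Signals are quantised to 16 bits over each channel's physical range and
#' written in one-second data records; the recording is truncated to a whole
#' number of seconds.
#'
#' @param data Numeric matrix, channels x samples, with row-name labels.
#' @param fs Sampling rate, Hz (integer).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(data, fs, path) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  fs <- as.integer(fs)
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record", call. = FALSE)
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8),
    pad_field("synthetic subject", 80),
    pad_field("synthetic cohort recording", 80),
    pad_field("01.01.17", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8),
    pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4),
    paste(pad_field(rownames(data), 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(pad_field(sprintf("%.2f", phys_min), 8), collapse = ""),
    paste(pad_field(sprintf("%.2f", phys_max), 8), collapse = ""),
    paste(rep(pad_field("-32768", 8), ns), collapse = ""),
    paste(rep(pad_field("32767", 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  ), con, eos = NULL)
  scale <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    seg <- data[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round((seg - phys_min) / scale) - 32768
    dig <- pmax(pmin(dig, 32767), -32768)
    # record layout: all samples of signal 1, then signal 2, ...
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `data` (channels x samples matrix, physical units,
#'   row-name labels), `fs` (per-record sample count over record duration)
#'   and `header` (named list of raw header fields).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  h <- list(
    version = rd(8), patient = rd(80), recording = rd(80),
    startdate = rd(8), starttime = rd(8),
    header_bytes = as.integer(rd(8)), reserved = rd(44),
    n_records = as.integer(rd(8)), record_duration = as.numeric(rd(8)),
    n_signals = as.integer(rd(4))
  )
  if (is.na(h$n_signals) || h$n_signals < 1 || is.na(h$n_records)) {
    stop("malformed EDF header: ", path, call. = FALSE)
  }
  ns <- h$n_signals
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  h$labels <- rdv(16)
  h$transducer <- rdv(80)
  h$dim <- rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  h$prefilter <- rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stop("EDF files with per-signal sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / h$record_duration
  data <- matrix(0, ns, h$n_records * spr[1])
  for (r in seq_len(h$n_records)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
      signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t(block)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- sweep(sweep(data, 1, dig_min) * scale, 1, phys_min, "+")
  rownames(data) <- h$labels
  list(data = data, fs = fs, header = h)
}
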