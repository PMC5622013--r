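#' Frequency band specification
#'
#' @param name Band name.
#' @param low,high Band edges in Hz; `0 < low < high` and `high` must stay
#'   below the Nyquist frequency of any recording it is applied to.
#' @return A `band_spec` list.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), low > 0, low < high)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Canonical EEG bands
#'
#' Delta 0.5-3.5 Hz, theta 4-7 Hz, alpha 8-12 Hz, beta 13-30 Hz. The delta
#' upper edge and the alpha band are configurable because conventions differ
#' between laboratories (alpha is sometimes taken to 12.5 Hz).
#'
#' @param delta_high Upper edge of delta, Hz.
#' @param alpha_high Upper edge of alpha, Hz.
#' @return Named list of [band_spec] objects.
#' @export
eeg_bands <- function(delta_high = 3.5, alpha_high = 12) {
  list(
    delta = band_spec("delta", 0.5, delta_high),
    theta = band_spec("theta", 4, 7),
    alpha = band_spec("alpha", 8, alpha_high),
    beta = band_spec("beta", 13, 30)
  )
}

#' Artifact rejection criteria
#'
#' An epoch is rejected if any scalp channel exceeds `amplitude_limit`
#' microvolts in absolute value, or if any scalp channel's absolute Pearson
#' correlation with the epoch's EOG trace exceeds `eog_correlation_limit`.
#'
#' @param amplitude_limit Critical amplitude in microvolts (default 150).
#' @param eog_correlation_limit Absolute-correlation limit in `[0, 1]`
#'   (default 0.7); set `NA` to disable the EOG criterion.
#' @return An `artifact_criteria` list.
#' @export
artifact_criteria <- function(amplitude_limit = 150, eog_correlation_limit = 0.7) {
  stopifnot(amplitude_limit > 0)
  if (!is.na(eog_correlation_limit)) {
    stopifnot(eog_correlation_limit >= 0, eog_correlation_limit <= 1)
  }
  structure(
    list(
      amplitude_limit = amplitude_limit,
      eog_correlation_limit = eog_correlation_limit
    ),
    class = "artifact_criteria"
  )
}

# FIR band-pass design: Hamming-window fir1, order from the transition-width
# rule of thumb (~3.3 cycles across the transition band), capped so filtfilt
# stays well-conditioned on the signal length.
design_bandpass <- function(band, fs, n_samples) {
  if (band$high >= fs / 2) {
    stop(sprintf(
      "band %s (%g-%g Hz) exceeds the Nyquist frequency %g Hz",
      band$name, band$low, band$high, fs / 2
    ), call. = FALSE)
  }
  transition <- if (band$low < 8) 1 else 2
  transition <- min(transition, band$low) # keep the low skirt above 0 Hz
  order <- ceiling(3.3 * fs / transition)
  order <- min(order, floor((n_samples - 1) / 3))
  if (order %% 2 == 1) order <- order - 1
  if (order < 8) stop("recording too short to band-pass filter", call. = FALSE)
  signal::fir1(order, c(band$low, band$high) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Filters every channel of a recording (EOG excluded) with a zero-phase
#' forward-backward FIR filter. Zero-phase filtering is used so that
#' band-limited causality estimates downstream are not distorted by filter
#' phase. Passband gain is within 10% of unity and stopband attenuation one
#' octave outside the band is below 0.1.
#'
#' @param rec An [eeg_recording].
#' @param band A [band_spec].
#' @return A filtered `eeg_recording` with a `band` attribute.
#' @export
bandpass <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  h <- design_bandpass(band, rec$fs, ncol(rec$data))
  out <- rec
  rows <- seq_len(nrow(rec$data))
  if (!is.null(rec$eog_index)) rows <- setdiff(rows, rec$eog_index)
  for (i in rows) {
    out$data[i, ] <- signal::filtfilt(as.numeric(h), 1, rec$data[i, ])
  }
  out$band <- band
  out
}

#' Cut a recording into fixed-length epochs
#'
#' Complete epochs only (no ragged tail). The EOG channel is epoched in
#' parallel and attached for artifact rejection.
#'
#' @param rec An [eeg_recording].
#' @param length_s Epoch length in seconds (default 4).
#' @param overlap Fractional overlap in `[0, 1)` (default 0).
#' @return An `epoch_set`: a list with `data` (epochs x channels x samples
#'   array), `eog` (epochs x samples matrix or NULL), `retained` mask,
#'   `band`, `fs`, `montage` and provenance labels.
#' @export
epoch <- function(rec, length_s = 4, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"), overlap >= 0, overlap < 1)
  L <- round(length_s * rec$fs)
  T <- ncol(rec$data)
  if (T < L) {
    stop(sprintf("recording (%d samples) shorter than one epoch (%d)", T, L),
      call. = FALSE
    )
  }
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, T - L + 1L, by = step)
  scalp <- scalp_data(rec)
  n_ch <- nrow(scalp)
  arr <- array(0, dim = c(length(starts), n_ch, L))
  for (e in seq_along(starts)) {
    arr[e, , ] <- scalp[, starts[e]:(starts[e] + L - 1L)]
  }
  eog <- NULL
  if (!is.null(rec$eog_index)) {
    eog <- matrix(0, length(starts), L)
    for (e in seq_along(starts)) {
      eog[e, ] <- rec$data[rec$eog_index, starts[e]:(starts[e] + L - 1L)]
    }
  }
  structure(
    list(
      data = arr, eog = eog, retained = rep(TRUE, length(starts)),
      band = rec$band, fs = rec$fs, montage = rec$montage,
      subject_id = rec$subject_id, group = rec$group,
      condition = rec$condition,
      rejection_log = tibble::tibble(
        epoch = integer(), reason = character()
      )
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set %s/%s/%s%s: %d epochs (%d retained) x %d ch x %d samples>\n",
    x$subject_id, x$group, x$condition,
    if (is.null(x$band)) "" else paste0(" [", x$band$name, "]"),
    dim(x$data)[1], sum(x$retained), dim(x$data)[2], dim(x$data)[3]
  ))
  invisible(x)
}

#' Automatic artifact rejection
#'
#' Marks an epoch as rejected iff its maximum absolute amplitude over any
#' scalp channel exceeds the critical value, or any channel is too similar
#' to the epoch's EOG trace (absolute Pearson correlation above the limit).
#' Rejection is recorded in `retained` and logged with a per-epoch reason;
#' applying the function twice is a no-op. An additional `exclude` index
#' vector supports manual exclusion (drowsiness/sleep screening is not
#' automated).
#'
#' @param ep An `epoch_set`.
#' @param criteria An [artifact_criteria].
#' @param eog Optional epochs x samples EOG matrix; defaults to the one
#'   attached by [epoch].
#' @param exclude Integer epoch indices to exclude manually.
#' @return The `epoch_set` with an updated mask and rejection log.
#' @export
reject_artifacts <- function(ep, criteria = artifact_criteria(), eog = NULL,
                             exclude = integer()) {
  stopifnot(inherits(ep, "epoch_set"))
  if (is.null(eog)) eog <- ep$eog
  use_eog <- !is.na(criteria$eog_correlation_limit)
  if (use_eog && is.null(eog)) {
    stop("EOG similarity criterion requested but no EOG traces available",
      call. = FALSE
    )
  }
  if (!is.null(eog) && nrow(eog) != dim(ep$data)[1]) {
    stop("EOG traces not aligned with epochs", call. = FALSE)
  }
  n_ep <- dim(ep$data)[1]
  reasons <- character(0)
  idx <- integer(0)
  retained <- rep(TRUE, n_ep)
  for (e in seq_len(n_ep)) {
    seg <- ep$data[e, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
    if (max(abs(seg)) > criteria$amplitude_limit) {
      retained[e] <- FALSE
      idx <- c(idx, e)
      reasons <- c(reasons, "amplitude")
      next
    }
    if (use_eog) {
      et <- eog[e, ]
      if (stats::sd(et) > 0) {
        cors <- apply(seg, 1, function(ch) {
          if (stats::sd(ch) == 0) 0 else stats::cor(ch, et)
        })
        if (max(abs(cors)) > criteria$eog_correlation_limit) {
          retained[e] <- FALSE
          idx <- c(idx, e)
          reasons <- c(reasons, "eog_similarity")
          next
        }
      }
    }
    if (e %in% exclude) {
      retained[e] <- FALSE
      idx <- c(idx, e)
      reasons <- c(reasons, "manual_exclusion")
    }
  }
  ep$retained <- ep$retained & retained
  ep$rejection_log <- dplyr::distinct(dplyr::bind_rows(
    ep$rejection_log,
    tibble::tibble(epoch = idx, reason = reasons)
  ))
  ep
}

# epochs surviving the mask, as a list of channels x samples matrices
retained_epochs <- function(ep) {
  keep <- which(ep$retained)
  lapply(keep, function(e) {
    m <- ep$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(ep$data)[2])
    m
  })
}

#' Preprocess a recording into band-limited, artifact-free epoch sets
#'
#' Artifact rejection is decided on the broadband epochs (amplitude
#' excursions and EOG similarity live in the unfiltered signal — a blink is
#' invisible after alpha-band filtering) and the resulting retained-epoch
#' mask is carried onto every band-filtered epoch set, whose epoch
#' boundaries are identical.
#'
#' @param rec An [eeg_recording].
#' @param bands Named list of [band_spec]s (default [eeg_bands]).
#' @param length_s,overlap Epoching parameters (see [epoch]).
#' @param criteria An [artifact_criteria].
#' @param exclude Manual epoch exclusion indices (see [reject_artifacts]).
#' @return Named list of `epoch_set`s, one per band, sharing the broadband
#'   rejection mask and log.
#' @export
preprocess_recording <- function(rec, bands = eeg_bands(), length_s = 4,
                                 overlap = 0, criteria = artifact_criteria(),
                                 exclude = integer()) {
  broadband <- reject_artifacts(
    epoch(rec, length_s, overlap), criteria,
    exclude = exclude
  )
  lapply(bands, function(b) {
    ep <- epoch(bandpass(rec, b), length_s, overlap)
    ep$retained <- broadband$retained
    ep$rejection_log <- broadband$rejection_log
    ep
  })
}

#' Write a rejection log
#'
#' @param ep An `epoch_set`.
#' @param path Output TSV path.
#' @return Invisibly, the log tibble.
#' @export
write_rejection_log <- function(ep, path) {
  readr::write_tsv(ep$rejection_log, path, progress = FALSE)
  invisible(ep$rejection_log)
}
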