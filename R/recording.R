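#' EEG recording container
#'
#' A channels-by-samples matrix in microvolts together with its montage,
#' sampling rate and study labels. The optional EOG channel is stored as an
#' extra row flagged by `eog_index`.
#'
#' @param data Numeric matrix, channels x samples (microvolts); row names are
#'   channel labels.
#' @param fs Sampling rate, Hz.
#' @param montage Montage tibble from [make_montage] (scalp channels only).
#' @param eog_index Row index of the EOG channel, or `NULL`.
#' @param subject_id,group,condition Study labels.
#' @param truth Optional [ground_truth] used to generate the data.
#' @param seed Optional integer provenance seed.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, montage, eog_index = NULL,
                          subject_id = NA_character_, group = NA_character_,
                          condition = NA_character_, truth = NULL, seed = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (!all(is.finite(data))) stop("non-finite samples in recording", call. = FALSE)
  expected <- nrow(montage) + as.integer(!is.null(eog_index))
  if (nrow(data) != expected) {
    stop(sprintf(
      "montage mismatch: %d data channels but montage implies %d",
      nrow(data), expected
    ), call. = FALSE)
  }
  structure(
    list(
      data = data, fs = fs, montage = montage, eog_index = eog_index,
      subject_id = subject_id, group = group, condition = condition,
      truth = truth, seed = seed
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording %s/%s/%s: %d ch x %d samples @ %g Hz%s>\n",
    x$subject_id, x$group, x$condition, nrow(x$data), ncol(x$data), x$fs,
    if (is.null(x$eog_index)) "" else " (+EOG)"
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# scalp-only data (drop EOG row)
scalp_data <- function(rec) {
  if (is.null(rec$eog_index)) rec$data else rec$data[-rec$eog_index, , drop = FALSE]
}

#' Read a recording from disk
#'
#' Reads an EDF or delimited-text fixture back into an [eeg_recording].
#' Channel labels, sampling rate and units are recovered from the file; the
#' EOG channel is identified by its label. For delimited text the sampling
#' rate must come from the manifest entry.
#'
#' @param path File path.
#' @param format "edf" or "txt" (guessed from the extension by default).
#' @param montage Montage the scalp channels must match.
#' @param manifest_entry Optional one-row data frame / list with `subject`,
#'   `group`, `condition`, `fs`, `eog_label` fields (as written by
#'   [write_fixture]).
#' @param eog_label Label of the EOG channel (default "EOG").
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = NULL, montage,
                           manifest_entry = NULL, eog_label = "EOG") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "txt"
  }
  if (!is.null(manifest_entry$eog_label)) eog_label <- manifest_entry$eog_label
  if (format == "edf") {
    e <- read_edf(path)
    data <- e$data
    fs <- e$fs
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(vapply(df, is.numeric, logical(1)))) {
      stop("malformed delimited recording (non-numeric columns): ", path,
        call. = FALSE
      )
    }
    data <- t(as.matrix(df))
    if (is.null(manifest_entry$fs)) {
      stop("delimited-text recordings need fs from the manifest", call. = FALSE)
    }
    fs <- manifest_entry$fs
  }
  if (!all(is.finite(data))) {
    stop("non-finite samples in file: ", path, call. = FALSE)
  }
  labels <- rownames(data)
  eog_index <- match(eog_label, labels)
  scalp_labels <- if (is.na(eog_index)) labels else labels[-eog_index]
  if (!identical(scalp_labels, montage$label)) {
    stop(sprintf(
      "montage mismatch in %s: %d scalp channels vs %d montage labels",
      path, length(scalp_labels), nrow(montage)
    ), call. = FALSE)
  }
  eeg_recording(
    data = data, fs = fs, montage = montage,
    eog_index = if (is.na(eog_index)) NULL else eog_index,
    subject_id = manifest_entry$subject %||% NA_character_,
    group = manifest_entry$group %||% NA_character_,
    condition = manifest_entry$condition %||% NA_character_
  )
}
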