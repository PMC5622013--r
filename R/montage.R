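#' Electrode montages
#'
#' Construct a scalp electrode montage as a tibble with one row per electrode:
#' label, scalp zone, hemisphere side, and schematic 2-D head coordinates for
#' topographic plotting.
#'
#' The 62-channel montage is the enlarged 10-20 layout used for high-density
#' clinical EEG (Fp1, Fpz, Fp2, F7, F3, ...). Published lists of this cap
#' usually omit one or two labels; here the lateral pairs are completed
#' symmetrically (P6 restores the P5/P6 pair) and the midline is closed with
#' Iz, giving 62 unique scalp positions. Smaller montages (4, 8, 16 channels)
#' are provided for testing and fast pipelines.
#'
#' Zones follow the letter convention: Fp/AF/F are frontal; FC/C central;
#' FT/T/TP temporal; CP/P parietal; PO/O/I occipital. Odd digits are left,
#' even digits right, and z (or Z) marks the midline.
#'
#' @param n_channels Number of scalp electrodes: one of 4, 5, 8, 16, 62.
#' @return A tibble with columns `label`, `zone`, `side`, `x`, `y` and class
#'   `eeg_montage`.
#' @examples
#' make_montage(4)
#' dplyr::count(make_montage(62), zone)
#' @export
make_montage <- function(n_channels) {
  labels <- switch(as.character(n_channels),
    "4" = c("F1", "C1", "P1", "O1"),
    "5" = c("F3", "C3", "T3", "P3", "O1"),
    "8" = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
    "16" = c(
      "Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
      "T3", "T4", "T5", "T6", "P3", "P4", "O1", "O2"
    ),
    "62" = c(
      "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
      "T3", "C3", "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6",
      "O1", "Oz", "O2", "FC2", "FC1", "CP1", "CP2", "PO3", "PO4",
      "FC6", "FC5", "CP5", "CP6", "AF7", "AF3", "AFZ", "AF4", "AF8",
      "F5", "F1", "F2", "F6", "FT7", "FC3", "FCZ", "FC4", "FT8",
      "C5", "C1", "C2", "C6", "TP7", "CP3", "CPZ", "CP4", "TP8",
      "P5", "P1", "P2", "P6", "PO7", "POZ", "PO8", "Iz"
    ),
    stop("unsupported channel count: ", n_channels,
      " (supported: 4, 5, 8, 16, 62)",
      call. = FALSE
    )
  )
  stopifnot(!anyDuplicated(labels))
  m <- tibble::tibble(
    label = labels,
    zone = unname(vapply(labels, electrode_zone, character(1))),
    side = unname(vapply(labels, electrode_side, character(1)))
  )
  coords <- electrode_coords(m$label)
  m$x <- coords$x
  m$y <- coords$y
  class(m) <- c("eeg_montage", class(m))
  m
}

#' @rdname make_montage
#' @param label Electrode label, e.g. "PO3".
#' @export
electrode_zone <- function(label) {
  stem <- sub("[0-9zZ]+$", "", label)
  zone <- c(
    Fp = "frontal", AF = "frontal", F = "frontal",
    FC = "central", C = "central",
    FT = "temporal", T = "temporal", TP = "temporal",
    CP = "parietal", P = "parietal",
    PO = "occipital", O = "occipital", I = "occipital"
  )[stem]
  if (is.na(zone)) stop("unknown electrode stem in label: ", label, call. = FALSE)
  unname(zone)
}

#' @rdname make_montage
#' @export
electrode_side <- function(label) {
  tail <- regmatches(label, regexpr("[0-9]+$|[zZ]$", label))
  if (length(tail) == 0) stop("label has no position suffix: ", label, call. = FALSE)
  if (grepl("[zZ]", tail)) return("midline")
  if (as.integer(tail) %% 2 == 1) "left" else "right"
}

# Schematic head coordinates: anterior-posterior row from the stem, lateral
# offset from the digit. Good enough for topographic scatter maps; not a
# geodesic cap model.
electrode_coords <- function(labels) {
  row_y <- c(
    Fp = 0.95, AF = 0.75, F = 0.55, FT = 0.35, FC = 0.35, C = 0, T = 0,
    TP = -0.35, CP = -0.35, P = -0.55, PO = -0.75, O = -0.95, I = -1.1
  )
  digit_x <- c("1" = 0.2, "2" = 0.2, "3" = 0.45, "4" = 0.45, "5" = 0.7,
    "6" = 0.7, "7" = 0.9, "8" = 0.9)
  x <- numeric(length(labels))
  y <- numeric(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    stem <- sub("[0-9zZ]+$", "", lab)
    suffix <- regmatches(lab, regexpr("[0-9]+$|[zZ]$", lab))
    y[i] <- row_y[[stem]]
    if (grepl("[zZ]", suffix)) {
      x[i] <- 0
    } else {
      d <- as.integer(suffix)
      # legacy temporal labels sit on the outer ring
      off <- if (stem %in% c("T") && d %in% c(3, 4)) 0.9
        else if (stem %in% c("T") && d %in% c(5, 6)) 0.85
        else digit_x[[as.character(d)]]
      x[i] <- if (d %% 2 == 1) -off else off
      if (stem == "T" && d %in% c(5, 6)) y[i] <- -0.55
    }
  }
  list(x = x, y = y)
}
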