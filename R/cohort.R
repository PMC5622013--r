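#' Specify a synthetic EEG cohort
#'
#' A cohort specification fixes everything needed to generate a reproducible
#' multichannel study: the montage, per-group sizes and coupling-graph
#' modification rules, per-condition rules, signal parameters and seeds.
#'
#' The default emulates a three-group visual-stimulation study: two
#' migraine-like groups of 19 subjects and a control-like group of 11, each
#' recorded at rest and under two checkerboard stimulation conditions
#' (0.5 and 2.0 cycles per degree). All groups share a random base coupling
#' graph; stimulation conditions add posterior-to-frontal couplings (the
#' posterior-to-frontal information flow stimulation evokes), and the
#' "MA"-like group additionally develops a segregated posterior cluster under
#' stimulation, some of whose couplings are quadratic.
#'
#' @param groups Named list; each element is `list(n_subjects =, add =,
#'   coupling_scale =)` where `add` is a list of motif additions
#'   (`list(motif =, n_edges =, coupling =, nonlinearity =, stim_only =)`).
#' @param conditions Named list of per-condition motif-addition lists; a
#'   condition named "rest" adds nothing by default.
#' @param n_channels Montage size (4, 8, 16 or 62).
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate, Hz.
#' @param base_n_edges,base_coupling Shared random background graph;
#'   `base_n_edges = NULL` scales the density with the montage
#'   (`n_channels / 2`).
#' @param band_profile List with `freq` (Hz) and `bw` (Hz): every channel is a
#'   stochastic AR(2) resonator at `freq` with half-power bandwidth `bw`.
#' @param noise_sd Innovation standard deviation (arbitrary units before the
#'   final microvolt scaling).
#' @param target_rms Per-channel RMS after scaling, in microvolts. The
#'   default 25 gives typical excursions of 50-100 microvolts, so the
#'   150-microvolt amplitude criterion fires on blink leakage and rare
#'   extreme epochs rather than on every clean epoch.
#' @param blink_rate Blinks per second on the EOG surrogate channel.
#' @param blink_amplitude Blink peak amplitude, microvolts.
#' @param blink_leak Fraction of the blink waveform leaking into frontal
#'   (Fp/AF) channels.
#' @param seed Master integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = NULL, conditions = NULL,
                        n_channels = 62, duration_s = 60, fs = 256,
                        base_n_edges = NULL, base_coupling = 0.25,
                        band_profile = list(freq = 10, bw = 2),
                        noise_sd = 1, target_rms = 25,
                        blink_rate = 0.1, blink_amplitude = 250,
                        blink_leak = 0.3, seed = 20170929) {
  if (is.null(groups)) {
    groups <- list(
      MA = list(
        n_subjects = 19,
        add = list(list(
          motif = "posterior_cluster", n_edges = 8, coupling = 0.4,
          nonlinearity = c(rep("linear", 6), rep("quadratic", 2)),
          stim_only = TRUE
        )),
        coupling_scale = 1
      ),
      MO = list(n_subjects = 19, add = list(), coupling_scale = 0.8),
      C = list(n_subjects = 11, add = list(), coupling_scale = 1)
    )
  }
  if (is.null(conditions)) {
    conditions <- list(
      rest = list(),
      stim_0.5cpd = list(list(
        motif = "posterior_to_frontal", n_edges = 10, coupling = 0.4,
        nonlinearity = "linear"
      )),
      stim_2.0cpd = list(list(
        motif = "posterior_to_frontal", n_edges = 14, coupling = 0.45,
        nonlinearity = "linear"
      ))
    )
  }
  montage <- make_montage(n_channels)
  # background density scales with the montage so small test montages stay
  # sparse enough for stable dynamics
  if (is.null(base_n_edges)) base_n_edges <- max(2L, round(n_channels / 2))
  max_freq <- max(band_profile$freq)
  stopifnot(
    all(vapply(groups, function(g) g$n_subjects > 0, logical(1))),
    fs > 2 * max_freq,
    duration_s * fs >= 10 * 5
  )
  structure(
    list(
      groups = groups, conditions = conditions, montage = montage,
      n_channels = n_channels, duration_s = duration_s, fs = fs,
      base_n_edges = base_n_edges, base_coupling = base_coupling,
      band_profile = band_profile, noise_sd = noise_sd,
      target_rms = target_rms, blink_rate = blink_rate,
      blink_amplitude = blink_amplitude, blink_leak = blink_leak,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# deterministic sub-seed derivation, kept within 32-bit range
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1664525 + as.numeric(p) + 1013904223) %% 2147483647
  as.integer(s)
}

linearised_radius <- function(truth, spec) {
  n <- truth$n_nodes
  fs <- spec$fs
  r <- exp(-pi * spec$band_profile$bw / fs)
  a1 <- 2 * r * cos(2 * pi * spec$band_profile$freq / fs)
  a2 <- -r^2
  lin <- truth$edges[truth$edges$nonlinearity == "linear", , drop = FALSE]
  C <- matrix(0, n, n)
  if (nrow(lin) > 0) C[cbind(lin$target, lin$source)] <- lin$strength
  comp <- rbind(
    cbind(diag(a1, n) + C, diag(a2, n)),
    cbind(diag(1, n), matrix(0, n, n))
  )
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Couplings between near-resonant AR(2) nodes amplify around cycles, so a
# dense motif (e.g. a reciprocal posterior cluster) can push the linearised
# system outside the unit circle. Cohort graphs are therefore scaled as a
# whole (relative edge strengths preserved) until the spectral radius is at
# most `margin`.
stabilise_truth <- function(truth, spec, margin = 0.99) {
  if (nrow(truth$edges) == 0) return(truth)
  for (i in 1:100) {
    if (linearised_radius(truth, spec) <= margin) return(truth)
    truth$edges$strength <- truth$edges$strength * 0.9
  }
  stop("could not stabilise the coupling graph", call. = FALSE)
}

# truth graph for one group x condition cell
cell_truth <- function(spec, group_label, condition_label) {
  g <- spec$groups[[group_label]]
  cond <- spec$conditions[[condition_label]]
  base_seed <- derive_seed(spec$seed, 1)
  truth <- simulate_truth(spec$n_channels, spec$base_n_edges, "random",
    seed = base_seed, montage = spec$montage, coupling = spec$base_coupling
  )
  if (!is.null(g$coupling_scale) && g$coupling_scale != 1) {
    truth$edges$strength <- truth$edges$strength * g$coupling_scale
  }
  is_stim <- !identical(condition_label, "rest")
  k <- 2L
  for (addition in cond) {
    add <- simulate_truth(spec$n_channels, addition$n_edges, addition$motif,
      seed = derive_seed(spec$seed, k, match(condition_label, names(spec$conditions))),
      montage = spec$montage, coupling = addition$coupling,
      nonlinearity = addition$nonlinearity,
      acyclic = identical(addition$motif, "posterior_cluster")
    )
    truth <- merge_truth(truth, add)
    k <- k + 1L
  }
  for (addition in g$add) {
    if (isTRUE(addition$stim_only) && !is_stim) next
    add <- simulate_truth(spec$n_channels, addition$n_edges, addition$motif,
      seed = derive_seed(spec$seed, 100L + match(group_label, names(spec$groups))),
      montage = spec$montage, coupling = addition$coupling,
      nonlinearity = addition$nonlinearity,
      acyclic = identical(addition$motif, "posterior_cluster")
    )
    truth <- merge_truth(truth, add)
  }
  stabilise_truth(truth, spec)
}

#' Simulate one multichannel recording from a ground-truth graph
#'
#' Each channel evolves as a stochastic AR(2) resonator at the cohort's band
#' profile frequency, driven by white innovations plus the sum over incoming
#' ground-truth edges of `strength * f(source value at lag 1)`, with `f`
#' identity (linear) or squaring (quadratic). A surrogate EOG channel — a
#' slow (< 4 Hz) AR(1) drift plus occasional high-amplitude blink pulses —
#' is appended as the last row, and a fraction of each blink leaks into
#' frontopolar channels so amplitude and EOG-similarity artifact rejection
#' both have something to reject. Channels are scaled by a common gain to a
#' realistic microvolt RMS.
#'
#' The linearised system (resonators plus linear couplings) is checked for
#' stability before simulation; a spectral radius at or above 1 is an error.
#'
#' @param truth A [ground_truth] whose `n_nodes` matches the montage.
#' @param spec A [cohort_spec].
#' @param subject_seed Integer; together with `spec$seed` determines the
#'   realisation bit-for-bit.
#' @param subject_id,group,condition Labels attached to the recording.
#' @return An `eeg_recording` object.
#' @export
simulate_recording <- function(truth, spec, subject_seed,
                               subject_id = paste0("S", subject_seed),
                               group = "synthetic", condition = "rest") {
  n <- truth$n_nodes
  if (n != nrow(spec$montage)) {
    stop("truth n_nodes does not match montage size", call. = FALSE)
  }
  fs <- spec$fs
  r <- exp(-pi * spec$band_profile$bw / fs)
  a1 <- 2 * r * cos(2 * pi * spec$band_profile$freq / fs)
  a2 <- -r^2
  lin <- truth$edges[truth$edges$nonlinearity == "linear", , drop = FALSE]
  quad <- truth$edges[truth$edges$nonlinearity == "quadratic", , drop = FALSE]
  C <- matrix(0, n, n)
  if (nrow(lin) > 0) C[cbind(lin$target, lin$source)] <- lin$strength
  # companion matrix of the linear part: [a1*I + C, a2*I; I, 0]
  comp <- rbind(
    cbind(diag(a1, n) + C, diag(a2, n)),
    cbind(diag(1, n), matrix(0, n, n))
  )
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf(
      "unstable autoregressive system (spectral radius %.3f >= 1)", rho
    ), call. = FALSE)
  }
  burn <- 512L
  nt <- as.integer(round(spec$duration_s * fs)) + burn
  seed <- derive_seed(spec$seed, subject_seed)
  x <- withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(n * nt, sd = spec$noise_sd), n, nt)
    xm <- matrix(0, n, nt)
    xm[, 1:2] <- eps[, 1:2]
    qt <- quad$target
    qs <- quad$source
    qw <- quad$strength
    for (t in 3:nt) {
      drive <- C %*% xm[, t - 1]
      if (length(qt) > 0) {
        drive[qt] <- drive[qt] + qw * xm[qs, t - 1]^2
      }
      xm[, t] <- a1 * xm[, t - 1] + a2 * xm[, t - 2] + drive + eps[, t]
    }
    # EOG surrogate: slow drift + blinks
    eog_innov <- stats::rnorm(nt)
    eog <- stats::filter(eog_innov, 0.995, method = "recursive")
    eog <- as.numeric(eog) / stats::sd(eog) * 30
    n_blinks <- stats::rpois(1, spec$blink_rate * spec$duration_s)
    blink_wave <- rep(0, nt)
    if (n_blinks > 0) {
      centers <- sample.int(nt - burn, n_blinks) + burn
      width <- round(0.15 * fs)
      tmpl <- exp(-((seq(-3 * width, 3 * width)) / width)^2 / 2)
      for (ct in centers) {
        lo <- max(1, ct - 3 * width)
        hi <- min(nt, ct + 3 * width)
        seg <- tmpl[seq(lo - ct + 3 * width + 1, hi - ct + 3 * width + 1)]
        amp <- spec$blink_amplitude * stats::runif(1, 0.8, 1.2)
        blink_wave[lo:hi] <- blink_wave[lo:hi] + amp * seg
      }
    }
    eog <- eog + blink_wave
    list(x = xm, eog = eog, blink = blink_wave)
  })
  xm <- x$x[, (burn + 1):nt, drop = FALSE]
  # per-channel scaling to the target RMS: coupled resonators can differ in
  # variance by orders of magnitude, and the causality index is invariant
  # under affine rescaling of any channel
  xm <- xm * (spec$target_rms / sqrt(rowMeans(xm^2)))
  frontopolar <- which(spec$montage$zone == "frontal" &
    grepl("^(Fp|AF)", spec$montage$label))
  blink_tail <- x$blink[(burn + 1):nt]
  if (length(frontopolar) > 0 && spec$blink_leak > 0) {
    xm[frontopolar, ] <- xm[frontopolar, ] +
      matrix(rep(spec$blink_leak * blink_tail, each = length(frontopolar)),
        nrow = length(frontopolar)
      )
  }
  data <- rbind(xm, EOG = x$eog[(burn + 1):nt])
  rownames(data) <- c(spec$montage$label, "EOG")
  stopifnot(all(is.finite(data)))
  eeg_recording(
    data = data, fs = fs, montage = spec$montage, eog_index = n + 1L,
    subject_id = subject_id, group = group, condition = condition,
    truth = truth, seed = seed
  )
}

#' Simulate a full cohort
#'
#' One recording per subject per condition, with ground truths stored per
#' group x condition cell.
#'
#' @param spec A [cohort_spec].
#' @return A list with `recordings` (list of `eeg_recording`), `truths`
#'   (named by "group/condition") and `manifest` (tibble).
#' @export
simulate_cohort <- function(spec) {
  recordings <- list()
  truths <- list()
  rows <- list()
  subj_counter <- 0L
  for (gl in names(spec$groups)) {
    g <- spec$groups[[gl]]
    for (cl in names(spec$conditions)) {
      truths[[paste(gl, cl, sep = "/")]] <- cell_truth(spec, gl, cl)
    }
    for (s in seq_len(g$n_subjects)) {
      subj_counter <- subj_counter + 1L
      sid <- sprintf("%s%02d", gl, s)
      for (cl in names(spec$conditions)) {
        rec <- simulate_recording(
          truths[[paste(gl, cl, sep = "/")]], spec,
          subject_seed = derive_seed(subj_counter, match(cl, names(spec$conditions))),
          subject_id = sid, group = gl, condition = cl
        )
        key <- paste(sid, cl, sep = "_")
        recordings[[key]] <- rec
        rows[[key]] <- tibble::tibble(
          subject = sid, group = gl, condition = cl,
          seed = rec$seed, n_channels = nrow(rec$data) - 1L, fs = spec$fs
        )
      }
    }
  }
  list(
    recordings = recordings, truths = truths,
    manifest = dplyr::bind_rows(rows)
  )
}

#' Write cohort fixtures to disk
#'
#' Writes each recording as either a 16-bit EDF file or a delimited text
#' matrix (header row = channel labels, one column per channel), plus a JSON
#' manifest mapping file to subject, group, condition and seed.
#'
#' @param recordings List of `eeg_recording` objects (or the result of
#'   [simulate_cohort]).
#' @param format "edf" or "txt".
#' @param path Output directory (created if missing).
#' @return Invisibly, a tibble manifest with a `file` column.
#' @export
write_fixture <- function(recordings, format = c("edf", "txt"), path) {
  format <- match.arg(format)
  if (!is.null(recordings$recordings)) recordings <- recordings$recordings
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create fixture directory: ", path, call. = FALSE)
  rows <- purrr::map(recordings, function(rec) {
    fname <- sprintf(
      "%s_%s.%s", rec$subject_id, gsub("[^A-Za-z0-9.]+", "-", rec$condition),
      format
    )
    fpath <- file.path(path, fname)
    if (format == "edf") {
      write_edf(rec$data, rec$fs, fpath)
    } else {
      df <- as.data.frame(t(rec$data))
      names(df) <- rownames(rec$data)
      readr::write_tsv(df, fpath, progress = FALSE)
    }
    tibble::tibble(
      file = fname, subject = rec$subject_id, group = rec$group,
      condition = rec$condition, fs = rec$fs,
      n_channels = nrow(rec$data), eog_label = "EOG",
      seed = if (is.null(rec$seed)) NA_integer_ else rec$seed
    )
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
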