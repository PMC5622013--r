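test_that("simulate_truth respects edge counts, seeds and motif zone constraints", {
  expect_equal(nrow(simulate_truth(10, 0, "random", seed = 1)$edges), 0)
  g1 <- simulate_truth(10, 12, "random", seed = 7)
  g2 <- simulate_truth(10, 12, "random", seed = 7)
  expect_identical(g1$edges, g2$edges)
  expect_false(identical(g1$edges, simulate_truth(10, 12, "random", seed = 8)$edges))
  expect_error(simulate_truth(4, 20, "random"), "exceeds")

  mont <- make_montage(62)
  pf <- simulate_truth(62, 20, "posterior_to_frontal", seed = 3, montage = mont)
  expect_equal(nrow(pf$edges), 20)
  expect_true(all(mont$zone[pf$edges$source] %in% c("parietal", "occipital")))
  expect_true(all(mont$zone[pf$edges$target] %in% c("frontal", "central")))
  pc <- simulate_truth(62, 10, "posterior_cluster", seed = 3, montage = mont)
  expect_true(all(mont$zone[c(pc$edges$source, pc$edges$target)] %in%
    c("parietal", "occipital")))
})

test_that("ground truth rejects self-edges and duplicates", {
  expect_error(
    ground_truth(3, tibble::tibble(
      source = 1, target = 1, strength = 0.3, nonlinearity = "linear"
    ))
  )
  expect_error(
    ground_truth(3, tibble::tibble(
      source = c(1, 1), target = c(2, 2), strength = 0.3,
      nonlinearity = "linear"
    )),
    "duplicate"
  )
})

test_that("simulated recordings are reproducible, finite and correctly shaped", {
  spec <- test_cohort_spec(n_channels = 8, duration_s = 8)
  tr <- simulate_truth(8, 0, "random", seed = 1)
  rec <- simulate_recording(tr, spec, subject_seed = 5)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$data), c(9, 8 * 256)) # 8 scalp + EOG
  expect_true(all(is.finite(rec$data)))
  rec2 <- simulate_recording(tr, spec, subject_seed = 5)
  expect_identical(rec$data, rec2$data)
  rec3 <- simulate_recording(tr, spec, subject_seed = 6)
  expect_false(identical(rec$data, rec3$data))
})

test_that("channel spectra peak inside the configured resonance band", {
  spec <- test_cohort_spec(n_channels = 8, duration_s = 16)
  rec <- simulate_recording(simulate_truth(8, 0, "random", seed = 1), spec, 1)
  peaks <- apply(rec$data[1:8, ], 1, function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = 256), plot = FALSE, spans = 15)
    sp$freq[which.max(sp$spec)]
  })
  expect_gte(mean(peaks >= 8 & peaks <= 12), 0.9)
})

test_that("a directed coupling shows up in the lagged cross-correlation", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 16)
  rec <- recording_from_edges(
    tibble::tibble(source = 1, target = 2, strength = 0.4, nonlinearity = "linear"),
    spec
  )
  x1 <- rec$data[1, ]
  x2 <- rec$data[2, ]
  T <- length(x1)
  fwd <- stats::cor(x1[-T], x2[-1]) # 1 leads 2
  rev <- stats::cor(x2[-T], x1[-1])
  expect_gt(fwd, rev)
})

test_that("an unstable coupling graph is rejected at construction", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 8)
  strong_cycle <- tibble::tibble(
    source = c(1, 2), target = c(2, 1), strength = 2,
    nonlinearity = "linear"
  )
  expect_error(
    recording_from_edges(strong_cycle, spec),
    "spectral radius"
  )
})

test_that("generated signals are stationary and scaled to the target RMS", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 16, target_rms = 25)
  rec <- simulate_recording(simulate_truth(4, 0, "random", seed = 2), spec, 3)
  expect_true(all(is.finite(rec$data)))
  expect_true(all(abs(sqrt(rowMeans(rec$data[1:4, ]^2)) - 25) < 1e-9))
  # no slow drift: halves of the recording have comparable variance
  half <- ncol(rec$data) %/% 2
  v1 <- apply(rec$data[1:4, 1:half], 1, var)
  v2 <- apply(rec$data[1:4, (half + 1):(2 * half)], 1, var)
  expect_true(all(v1 / v2 < 10 & v2 / v1 < 10))
})

test_that("default cohort design has the study's group sizes and contrasts", {
  spec <- cohort_spec(duration_s = 4) # full 62-channel design, short signals
  co <- simulate_cohort(spec)
  expect_equal(length(co$recordings), (19 + 19 + 11) * 3)
  subjects <- dplyr::distinct(co$manifest, subject, group)
  expect_equal(sort(dplyr::count(subjects, group)$n), c(11, 19, 19))
  # MA-like group under stimulation carries a posterior cluster that the
  # control-like group lacks
  mont <- spec$montage
  ma_stim <- co$truths[["MA/stim_0.5cpd"]]$edges
  c_stim <- co$truths[["C/stim_0.5cpd"]]$edges
  post_edge <- function(e) {
    mont$zone[e$source] %in% c("parietal", "occipital") &
      mont$zone[e$target] %in% c("parietal", "occipital")
  }
  expect_gt(sum(post_edge(ma_stim)), sum(post_edge(c_stim)))
  # single-subject single-condition spec gives one recording
  co1 <- simulate_cohort(test_cohort_spec(n_channels = 4, duration_s = 4))
  expect_equal(length(co1$recordings), 1)
})

test_that("cohort generation is deterministic for fixed seeds", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 4, n_subjects = 2,
    base_n_edges = 2)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(
    lapply(co1$recordings, `[[`, "data"),
    lapply(co2$recordings, `[[`, "data")
  )
})

test_that("EDF fixtures round-trip and have a valid independently-parsed header", {
  spec <- test_cohort_spec(n_channels = 8, duration_s = 4)
  co <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- write_fixture(co, "edf", dir)
  f <- file.path(dir, manifest$file[1])

  # independent header parse with readBin/readChar, no package code
  con <- file(f, "rb")
  version <- trimws(readChar(con, 8))
  seek(con, 236)
  n_records <- as.integer(readChar(con, 8))
  record_dur <- as.numeric(readChar(con, 8))
  n_signals <- as.integer(readChar(con, 4))
  labels <- trimws(vapply(1:n_signals, function(i) readChar(con, 16), ""))
  close(con)
  expect_equal(version, "0")
  expect_equal(n_signals, 9) # 8 scalp + EOG
  expect_equal(record_dur, 1)
  expect_equal(labels[1], "F3")
  expect_equal(labels[9], "EOG")
  info <- file.info(f)
  expect_equal(info$size, 256 + 9 * 256 + n_records * 9 * 256 * 2)

  rec <- co$recordings[[1]]
  back <- read_recording(f, montage = spec$montage,
    manifest_entry = as.list(manifest[1, ]))
  expect_equal(back$fs, 256)
  expect_lt(max(abs(back$data - rec$data[, 1:ncol(back$data)])), 0.05)
  expect_equal(back$subject_id, rec$subject_id)
})

test_that("delimited-text fixtures carry a channel-label header and round-trip", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 4)
  co <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- write_fixture(co, "txt", dir)
  f <- file.path(dir, manifest$file[1])
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(header, c("F1", "C1", "P1", "O1", "EOG"))
  back <- read_recording(f, montage = spec$montage,
    manifest_entry = as.list(manifest[1, ]))
  expect_lt(max(abs(back$data - co$recordings[[1]]$data)), 1e-8)
  # manifest is valid JSON with the study labels
  j <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(j[[1]]$group, "A")
})
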