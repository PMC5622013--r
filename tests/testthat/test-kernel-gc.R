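test_that("time-delay embedding lays out lags and targets by construction", {
  e <- embed_series(c(1, 2, 3, 4), 2)
  expect_equal(e$states, rbind(c(2, 1), c(3, 2)))
  expect_equal(e$target, c(3, 4))
  expect_equal(nrow(embed_series(rnorm(100), 5)$states), 95)
  const <- embed_series(rep(2, 10), 3)
  expect_true(all(const$states == 2))
  expect_error(embed_series(1:3, 5), "exceed")
})

test_that("linear-kernel unfiltered GC equals the OLS variance-ratio oracle", {
  set.seed(101)
  cfg <- gc_config(m = 3, filter = FALSE)
  for (i in 1:10) {
    T <- 600
    y <- rnorm(T)
    x <- as.numeric(stats::filter(0.3 * c(0, y[-T]) + rnorm(T), 0.4,
      method = "recursive"))
    ex <- embed_series(x, 3)
    dy <- embed_series(y, 3)$states
    d <- as.numeric(filtered_gc(ex$target, ex$states, cbind(ex$states, dy), cfg))
    oracle <- ols_granger_oracle(ex$target, ex$states, cbind(ex$states, dy))
    expect_lt(abs(d - oracle), 1e-6)
  }
})

test_that("the analytic VAR coupling is recovered at its closed-form delta", {
  # x_t = 0.5 y_{t-1} + e_x with unit variances: restricted residual variance
  # 1.25, full 1.0 -> delta = 0.25 / 1.25 = 0.2
  set.seed(77)
  ds <- replicate(10, {
    T <- 2000
    y <- rnorm(T)
    x <- c(0, 0.5 * y[-T]) + rnorm(T)
    ex <- embed_series(x, 2)
    dy <- embed_series(y, 2)$states
    as.numeric(filtered_gc(ex$target, ex$states, cbind(ex$states, dy),
      gc_config(m = 2)))
  })
  expect_lt(abs(mean(ds) - 0.2), 0.03)
})

test_that("independent channels give zero delta almost always", {
  set.seed(55)
  cfg <- gc_config(m = 2)
  ds <- replicate(60, {
    T <- 1000
    ex <- embed_series(rnorm(T), 2)
    dy <- embed_series(rnorm(T), 2)$states
    as.numeric(filtered_gc(ex$target, ex$states, cbind(ex$states, dy), cfg))
  })
  expect_gte(mean(ds == 0), 0.9)
  expect_lt(mean(ds), 0.01)
})

test_that("quadratic coupling is invisible to the linear kernel but not the polynomial", {
  set.seed(33)
  res <- replicate(30, {
    T <- 1000
    y <- rnorm(T)
    x <- c(0, 0.5 * y[-T]^2) + rnorm(T)
    ex <- embed_series(x, 2)
    dy <- embed_series(y, 2)$states
    full <- cbind(ex$states, dy)
    c(
      lin = as.numeric(filtered_gc(ex$target, ex$states, full, gc_config(m = 2))),
      pol = as.numeric(filtered_gc(ex$target, ex$states, full,
        gc_config(m = 2, kernel = "poly")))
    )
  })
  expect_gte(mean(res["pol", ] > 0.02), 0.9)
  expect_gte(mean(res["lin", ] <= 0.02), 0.9)
})

test_that("the gaussian kernel separates a coupled driver from an independent one", {
  set.seed(21)
  cfg <- gc_config(m = 2, kernel = "gaussian")
  res <- replicate(5, {
    T <- 300
    y <- rnorm(T)
    x <- c(0, 0.6 * y[-T]) + rnorm(T)
    ex <- embed_series(x, 2)
    dy <- embed_series(y, 2)$states
    d <- as.numeric(filtered_gc(ex$target, ex$states, cbind(ex$states, dy), cfg))
    d0 <- as.numeric(filtered_gc(ex$target, ex$states,
      cbind(ex$states, embed_series(rnorm(T), 2)$states), cfg))
    c(d = d, d0 = d0)
  })
  expect_gt(mean(res["d", ]), mean(res["d0", ]))
  expect_gte(mean(res["d", ] > 0.01), 0.8)
})

test_that("delta is bounded, conservative under filtering and scale-invariant", {
  set.seed(8)
  for (i in 1:10) {
    T <- 400
    y <- rnorm(T)
    x <- c(0, 0.4 * y[-T]) + rnorm(T)
    ex <- embed_series(x, 4)
    dy <- embed_series(y, 4)$states
    full <- cbind(ex$states, dy)
    df <- as.numeric(filtered_gc(ex$target, ex$states, full, gc_config(m = 4)))
    du <- as.numeric(filtered_gc(ex$target, ex$states, full,
      gc_config(m = 4, filter = FALSE)))
    expect_gte(df, 0)
    expect_lt(du, 1)
    expect_lte(df, du + 1e-12)
    # affine rescaling of driver and target leaves delta unchanged
    d2 <- as.numeric(filtered_gc(5 * ex$target + 3, ex$states * 2 + 1,
      cbind(ex$states * 2 + 1, dy * 0.1 - 4), gc_config(m = 4)))
    expect_lt(abs(df - d2), 1e-8)
  }
})

test_that("transfer entropy follows the Gaussian equivalence mapping", {
  expect_equal(transfer_entropy(0), 0)
  expect_equal(transfer_entropy(0.2), -0.5 * log(0.8), tolerance = 1e-12)
  expect_gt(transfer_entropy(0.5), transfer_entropy(0.2))
  expect_error(transfer_entropy(1), "delta")
  expect_error(transfer_entropy(-0.1), "delta")
  m <- matrix(c(0, 0.2, 0.5, 0), 2, 2)
  expect_equal(transfer_entropy(m), -0.5 * log(1 - m))
})

test_that("the Gaussian-equivalence TE agrees with a histogram estimator", {
  set.seed(12)
  T <- 20000
  y <- rnorm(T)
  x <- c(0, 0.6 * y[-T]) + rnorm(T)
  ex <- embed_series(x, 1)
  dy <- embed_series(y, 1)$states
  d <- as.numeric(filtered_gc(ex$target, ex$states, cbind(ex$states, dy),
    gc_config(m = 1, filter = FALSE)))
  te_gauss <- transfer_entropy(d)
  te_hist <- hist_te_oracle(x, y, n_bins = 8)
  # binned plug-in estimators are biased; agreement is loose but real
  expect_lt(abs(te_gauss - te_hist) / te_gauss, 0.35)
})

test_that("degenerate inputs are handled without numerical failure", {
  ex <- embed_series(rep(1, 50), 2)
  dy <- embed_series(rnorm(50), 2)$states
  expect_warning(
    d <- filtered_gc(ex$target, ex$states, cbind(ex$states, dy), gc_config(m = 2)),
    "constant"
  )
  expect_equal(as.numeric(d), 0)
  # duplicate channel as driver and target: no crash, flagged degenerate
  x <- rnorm(100)
  exx <- embed_series(x, 2)
  d2 <- filtered_gc(exx$target, exx$states, cbind(exx$states, exx$states),
    gc_config(m = 2))
  expect_equal(as.numeric(d2), 0)
  expect_true(isTRUE(attr(d2, "degenerate")))
})

test_that("gc_matrix ranks a true edge top and respects orientation", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 16)
  rec <- recording_from_edges(
    tibble::tibble(source = 1, target = 2, strength = 0.4, nonlinearity = "linear"),
    spec
  )
  ep <- reject_artifacts(epoch(rec, 4))
  cm <- gc_matrix(ep, gc_config(m = 5))
  expect_s3_class(cm, "connectivity_matrix")
  expect_true(all(diag(cm$delta) == 0))
  expect_true(all(cm$delta >= 0 & cm$delta < 1))
  expect_equal(cm$te, -0.5 * log(1 - cm$delta))
  off <- cm$delta[row(cm$delta) != col(cm$delta)]
  # delta[target = 2, driver = 1] is the largest entry
  expect_equal(cm$delta[2, 1], max(off))
  expect_equal(cm$n_epochs_used, 4)
})

test_that("gc_matrix with zero coupling keeps the mean off-diagonal delta small", {
  spec <- test_cohort_spec(n_channels = 5, duration_s = 16, seed = 19)
  rec <- simulate_recording(simulate_truth(5, 0, "random", seed = 1), spec, 2)
  cm <- gc_matrix(reject_artifacts(epoch(rec, 4)), gc_config(m = 5))
  off <- cm$delta[row(cm$delta) != col(cm$delta)]
  expect_lt(mean(off), 0.02)
})

test_that("surrogate significance masks are reproducible and catch strong edges", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 16)
  rec <- recording_from_edges(
    tibble::tibble(source = 1, target = 2, strength = 0.6, nonlinearity = "linear"),
    spec, subject_seed = 3
  )
  ep <- reject_artifacts(epoch(rec, 4))
  cm <- gc_matrix(ep, gc_config(m = 5))
  m1 <- significance_mask(cm, ep, n_surrogates = 19, alpha = 0.05, seed = 42)
  m2 <- significance_mask(cm, ep, n_surrogates = 19, alpha = 0.05, seed = 42)
  expect_identical(m1$sig_mask, m2$sig_mask)
  expect_true(m1$sig_mask[2, 1])
  expect_error(
    significance_mask(cm, ep, n_surrogates = 10, alpha = 0.05),
    "surrogates"
  )
})

test_that("edges of a 10-node graph are recovered with high sensitivity and controlled FPR", {
  set.seed(606)
  n <- 10
  T <- 4000
  # acyclic coupling pattern (stable by construction), AR(1) self-terms
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- sample(nrow(pairs), 12)
  C <- matrix(0, n, n)
  C[pairs[idx, , drop = FALSE]] <- 0.4 # C[i, j]: i drives j
  X <- matrix(0, n, T)
  X[, 1] <- rnorm(n)
  for (t in 2:T) {
    X[, t] <- 0.3 * X[, t - 1] + t(C) %*% X[, t - 1] + rnorm(n)
  }
  ep <- epoch_set_from_matrix(X, epoch_len = 1000)
  # conditional estimation: in a 12-edge graph, chains make downstream
  # channels genuinely predictable from upstream ones pairwise, so only
  # conditioning on the remaining channels makes ground-truth edges the
  # correct positives
  cm <- gc_matrix(ep, gc_config(m = 2, conditioning = "conditional"))
  cm <- significance_mask(cm, ep, n_surrogates = 19, alpha = 0.05, seed = 17)
  truth_mask <- t(C) > 0 # row = target, column = driver
  sens <- sum(cm$sig_mask & truth_mask) / sum(truth_mask)
  fpr <- sum(cm$sig_mask & !truth_mask & row(truth_mask) != col(truth_mask)) /
    (n * (n - 1) - sum(truth_mask))
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05 + 1.96 * sqrt(0.05 * 0.95 / (n * (n - 1) - 12)))
})

test_that("conditional-mode estimation explains away an indirect chain", {
  # chain 1 -> 2 -> 3: bivariate analysis sees 1 -> 3, conditioning on
  # channel 2 should shrink it
  spec <- test_cohort_spec(n_channels = 4, duration_s = 16)
  rec <- recording_from_edges(
    tibble::tibble(source = c(1, 2), target = c(2, 3), strength = 0.5,
      nonlinearity = "linear"),
    spec, subject_seed = 8
  )
  ep <- reject_artifacts(epoch(rec, 4))
  biv <- gc_matrix(ep, gc_config(m = 3, conditioning = "bivariate"))
  cond <- gc_matrix(ep, gc_config(m = 3, conditioning = "conditional"))
  expect_lt(cond$delta[3, 1], biv$delta[3, 1] + 1e-9)
  # the direct links survive conditioning
  expect_gt(cond$delta[2, 1], 0)
  expect_gt(cond$delta[3, 2], 0)
})

test_that("connectivity matrices serialise with orientation metadata", {
  spec <- test_cohort_spec(n_channels = 4, duration_s = 8)
  rec <- simulate_recording(simulate_truth(4, 2, "random", seed = 2), spec, 1)
  ep <- reject_artifacts(epoch(rec, 4))
  cm <- gc_matrix(ep, gc_config(m = 3))
  dir <- withr::local_tempdir()
  paths <- write_connectivity(cm, dir)
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[["meta"]])
  expect_match(meta$orientation, "row = target")
  back <- as.matrix(utils::read.table(paths[["delta"]], sep = "\t", header = TRUE,
    row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(cm$delta), tolerance = 1e-12)
})
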