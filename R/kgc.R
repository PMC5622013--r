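#' Kernel Granger causality configuration
#'
#' @param m Embedding order (number of lags), default 5.
#' @param kernel "linear", "poly" (inhomogeneous polynomial) or "gaussian".
#' @param degree Polynomial degree for the "poly" kernel (default 2).
#' @param sigma Gaussian kernel width; `NULL` uses the median pairwise
#'   distance of the state vectors (median heuristic).
#' @param eigenvalue_floor Fraction of the largest eigenvalue below which a
#'   Gram eigendirection is treated as numerically outside the span
#'   (default 1e-6).
#' @param alpha Significance level of the per-eigenvector Pearson filter
#'   (default 0.05), Bonferroni-corrected over the number of complement
#'   directions tested.
#' @param filter If `FALSE`, the eigenvector filter is disabled and the index
#'   sums all squared residual-complement correlations (this is the plain
#'   variance-ratio Granger statistic for the linear kernel).
#' @param conditioning "bivariate" (each pair in isolation) or "conditional"
#'   (all other channels' lags appended to both models). Conditional mode is
#'   intended for small montages.
#' @return A `gc_config` list.
#' @export
gc_config <- function(m = 5, kernel = c("linear", "poly", "gaussian"),
                      degree = 2, sigma = NULL, eigenvalue_floor = 1e-6,
                      alpha = 0.05, filter = TRUE,
                      conditioning = c("bivariate", "conditional")) {
  kernel <- match.arg(kernel)
  conditioning <- match.arg(conditioning)
  stopifnot(m >= 1, degree >= 1, alpha > 0, alpha < 1, eigenvalue_floor > 0)
  if (!is.null(sigma)) stopifnot(sigma > 0)
  structure(
    list(
      m = as.integer(m), kernel = kernel, degree = degree, sigma = sigma,
      eigenvalue_floor = eigenvalue_floor, alpha = alpha, filter = filter,
      conditioning = conditioning
    ),
    class = "gc_config"
  )
}

#' Time-delay embedding
#'
#' Builds the lagged state matrix and aligned target vector used by the
#' Granger models: row `t` of the state matrix holds
#' `(x[t+m-1], ..., x[t])` (lag 1 first) and the target is `x[t+m]`.
#'
#' @param series Numeric vector of length `T > m`.
#' @param m Number of lags.
#' @return List with `states` (`(T-m) x m` matrix) and `target`
#'   (length `T-m` vector).
#' @export
embed_series <- function(series, m) {
  T <- length(series)
  if (T <= m) stop("series length must exceed the embedding order", call. = FALSE)
  n <- T - m
  states <- matrix(0, n, m)
  for (lag in seq_len(m)) {
    states[, lag] <- series[(m - lag + 1):(T - lag)]
  }
  list(states = states, target = series[(m + 1):T])
}

# explicit inhomogeneous polynomial degree-2 feature map:
# all x_i and x_i x_j (i <= j); the constant is dropped by centering
poly2_features <- function(x) {
  d <- ncol(x)
  idx <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  quad <- x[, idx[, 1], drop = FALSE] * x[, idx[, 2], drop = FALSE]
  cbind(x, quad)
}

# Orthonormal basis (columns) of the centered kernel feature span.
# For linear/poly kernels this is the left-singular basis of the centered
# explicit feature matrix; for the gaussian kernel, the eigenvectors of the
# double-centered Gram matrix. Both carry the eigenvalue floor: directions
# whose Gram eigenvalue is below floor x largest are excluded from the span.
span_basis <- function(states, config) {
  floor_frac <- config$eigenvalue_floor
  if (config$kernel == "gaussian") {
    D2 <- as.matrix(stats::dist(states))^2
    sigma <- config$sigma
    if (is.null(sigma)) {
      med <- stats::median(sqrt(D2[upper.tri(D2)]))
      sigma <- if (is.finite(med) && med > 0) med else 1
    }
    K <- exp(-D2 / (2 * sigma^2))
    n <- nrow(K)
    H <- diag(n) - matrix(1 / n, n, n)
    Kc <- H %*% K %*% H
    eg <- eigen(Kc, symmetric = TRUE)
    keep <- eg$values > floor_frac * max(eg$values[1], 0) & eg$values > 0
    return(eg$vectors[, keep, drop = FALSE])
  }
  phi <- switch(config$kernel,
    linear = states,
    poly = {
      if (config$degree != 2) {
        stop("only degree 2 is implemented for the polynomial kernel",
          call. = FALSE
        )
      }
      poly2_features(states)
    }
  )
  phi <- scale(phi, center = TRUE, scale = FALSE)
  sv <- svd(phi, nu = min(dim(phi)), nv = 0)
  ev <- sv$d^2
  keep <- ev > floor_frac * max(ev[1], 0) & sv$d > 0
  sv$u[, keep, drop = FALSE]
}

# complement of span(U_r) within span(U_f): orthonormal directions of the
# full model not predictable by the restricted one
span_complement <- function(U_r, U_f, tol) {
  W <- U_f - U_r %*% (crossprod(U_r, U_f))
  sv <- svd(W, nv = 0)
  keep <- sv$d > tol
  sv$u[, keep, drop = FALSE]
}

#' Filtered kernel Granger causality index
#'
#' The directed index `delta` for a driver's influence on a target: the
#' centered target is regressed (in the kernel feature space) on the
#' restricted state matrix, and the restricted residual is correlated with
#' each orthonormal direction the full model adds beyond the restricted span.
#' Only directions whose Pearson correlation with the residual is significant
#' at `alpha` (Bonferroni-corrected over the directions tested) contribute;
#' `delta` is the sum of their squared correlations, the fraction of residual
#' variance the driver explains. With the filter disabled and a linear
#' kernel this is exactly the ordinary-least-squares Granger variance-ratio
#' statistic.
#'
#' @param target Numeric vector (contemporaneous samples).
#' @param restricted_states State matrix of the restricted model (driver
#'   excluded), rows aligned with `target`.
#' @param full_states State matrix of the full model (driver's lags
#'   appended).
#' @param config A [gc_config].
#' @return `delta` in `[0, 1)`, with attribute `n_directions` (complement
#'   directions tested). Degenerate inputs (constant target, or a driver
#'   adding nothing to the span) give 0.
#' @export
filtered_gc <- function(target, restricted_states, full_states, config = gc_config()) {
  restricted_states <- as.matrix(restricted_states)
  full_states <- as.matrix(full_states)
  y <- target - mean(target)
  n <- length(y)
  if (sum(y^2) <= .Machine$double.eps * n) {
    warning("constant target: delta set to 0")
    return(structure(0, n_directions = 0L))
  }
  if (config$kernel == "gaussian") {
    return(gram_gc(y, restricted_states, full_states, config))
  }
  # full = restricted with the driver's lags appended (the estimation
  # contract); the driver block supplies the complement directions
  p <- ncol(restricted_states)
  stopifnot(ncol(full_states) > p)
  D <- full_states[, (p + 1):ncol(full_states), drop = FALSE]
  cache <- target_cache(target, restricted_states, config)
  gc_from_cache(cache, D, config)
}

# Gram-matrix route (gaussian kernel): eigenvectors of the double-centered
# Gram matrices play the role of the feature bases.
gram_gc <- function(y, restricted_states, full_states, config) {
  n <- length(y)
  U_r <- span_basis(restricted_states, config)
  U_f <- span_basis(full_states, config)
  e <- as.numeric(y - U_r %*% crossprod(U_r, y))
  sse <- sum(e^2)
  if (sse <= sum(y^2) * 1e-12) {
    return(structure(0, n_directions = 0L))
  }
  Tc <- span_complement(U_r, U_f, sqrt(config$eigenvalue_floor))
  k <- ncol(Tc)
  if (k == 0) return(structure(0, n_directions = 0L, degenerate = TRUE))
  r2 <- pmin(as.numeric(crossprod(Tc, e))^2 / sse, 1 - 1e-15)
  if (config$filter) {
    tstat <- sqrt(r2 * (n - 2) / (1 - r2))
    pvals <- 2 * stats::pt(-tstat, df = n - 2)
    delta <- sum(r2[pvals < config$alpha / k])
  } else {
    delta <- sum(r2)
  }
  structure(max(0, min(delta, 1 - 1e-12)), n_directions = k)
}

#' Transfer entropy from a Granger index
#'
#' For Gaussian linear processes the transfer entropy equals
#' `-0.5 * log(1 - delta)` nats, where `delta` is the fraction of restricted
#' residual variance explained by the driver. The mapping is strictly
#' increasing, so GC and TE order links identically.
#'
#' @param delta Granger index (or matrix of indices) in `[0, 1)`.
#' @return Transfer entropy in nats, same shape as `delta`.
#' @export
transfer_entropy <- function(delta) {
  if (any(delta < 0 | delta >= 1)) {
    stop("delta must lie in [0, 1)", call. = FALSE)
  }
  -0.5 * log(1 - delta)
}

# ---- fast cached path -------------------------------------------------
# For bivariate estimation with an explicit feature map (linear/poly), the
# restricted model depends only on the target, so its basis and residual are
# computed once per (epoch, target) and reused across drivers and surrogate
# shifts. The complement directions are obtained from the feature columns
# the driver adds beyond the restricted span (for the degree-2 polynomial
# map: the driver lags, their squares/products, and driver x target-lag
# cross products) — the same span as the reference path in [filtered_gc].

target_cache <- function(target, restricted_states, config) {
  y <- target - mean(target)
  U_r <- span_basis(restricted_states, config)
  e <- y - U_r %*% crossprod(U_r, y)
  list(
    U_r = U_r, e = as.numeric(e), sse = sum(e^2), ssy = sum(y^2),
    n = length(y), R = restricted_states
  )
}

# feature columns the driver adds beyond the restricted model's
driver_extra_features <- function(R, D, config) {
  if (config$kernel == "linear") return(D)
  dd <- ncol(D)
  idx <- which(upper.tri(matrix(0, dd, dd), diag = TRUE), arr.ind = TRUE)
  quad <- D[, idx[, 1], drop = FALSE] * D[, idx[, 2], drop = FALSE]
  cross <- do.call(cbind, lapply(seq_len(ncol(R)), function(k) R[, k] * D))
  cbind(D, quad, cross)
}

# orthonormal basis of the centered columns of X, eigenvalue floor applied
column_basis <- function(X, floor_frac) {
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nv = 0)
  ev <- sv$d^2
  keep <- ev > floor_frac * max(ev[1], 0) & sv$d > 0
  sv$u[, keep, drop = FALSE]
}

gc_from_cache <- function(cache, D, config, U_e = NULL) {
  if (cache$ssy <= .Machine$double.eps * cache$n ||
    cache$sse <= cache$ssy * 1e-12) {
    return(structure(0, n_directions = 0L))
  }
  if (is.null(U_e)) {
    U_e <- column_basis(
      driver_extra_features(cache$R, D, config), config$eigenvalue_floor
    )
  }
  Tc <- span_complement(cache$U_r, U_e, sqrt(config$eigenvalue_floor))
  k <- ncol(Tc)
  if (k == 0) return(structure(0, n_directions = 0L, degenerate = TRUE))
  r2 <- as.numeric(crossprod(Tc, cache$e))^2 / cache$sse
  r2 <- pmin(r2, 1 - 1e-15)
  if (config$filter) {
    tstat <- sqrt(r2 * (cache$n - 2) / (1 - r2))
    pvals <- 2 * stats::pt(-tstat, df = cache$n - 2)
    delta <- sum(r2[pvals < config$alpha / k])
  } else {
    delta <- sum(r2)
  }
  structure(max(0, min(delta, 1 - 1e-12)), n_directions = k)
}

use_fast_path <- function(config) {
  config$conditioning == "bivariate" && config$kernel != "gaussian"
}

# state matrices for the (j -> i) pair within one epoch's lag array.
# lags: list per channel of (T-m) x m lag matrices; conditioning per config.
pair_states <- function(lags, i, j, config) {
  if (config$conditioning == "bivariate") {
    restricted <- lags[[i]]
  } else {
    others <- setdiff(seq_along(lags), c(i, j))
    restricted <- do.call(cbind, c(list(lags[[i]]), lags[others]))
  }
  list(restricted = restricted, full = cbind(restricted, lags[[j]]))
}

#' Connectivity matrix from an epoch set
#'
#' Estimates the filtered kernel Granger index for every ordered channel pair
#' within each retained epoch and averages over epochs (epochs are never
#' concatenated, so the artifact-rejection boundaries are respected).
#' Orientation: `delta[i, j]` is the flow from driver `j` into target `i`
#' (row = target, column = driver). Transfer entropy is filled in via
#' [transfer_entropy]; the significance mask starts all-`FALSE` and is
#' populated by [significance_mask].
#'
#' @param ep An `epoch_set` with at least one retained epoch.
#' @param config A [gc_config].
#' @return A `connectivity_matrix` object.
#' @export
gc_matrix <- function(ep, config = gc_config()) {
  stopifnot(inherits(ep, "epoch_set"))
  eps_list <- retained_epochs(ep)
  if (length(eps_list) == 0) stop("no retained epochs", call. = FALSE)
  n_ch <- dim(ep$data)[2]
  m <- config$m
  acc <- matrix(0, n_ch, n_ch)
  degen <- matrix(FALSE, n_ch, n_ch)
  fast <- use_fast_path(config)
  for (seg in eps_list) {
    emb <- lapply(seq_len(n_ch), function(c) embed_series(seg[c, ], m))
    lags <- lapply(emb, `[[`, "states")
    linear <- fast && config$kernel == "linear"
    U_es <- if (linear) {
      lapply(lags, column_basis, floor_frac = config$eigenvalue_floor)
    }
    for (i in seq_len(n_ch)) {
      yi <- emb[[i]]$target
      cache <- if (fast) target_cache(yi, lags[[i]], config)
      for (j in seq_len(n_ch)) {
        if (i == j) next
        d <- if (fast) {
          gc_from_cache(cache, lags[[j]], config,
            U_e = if (linear) U_es[[j]]
          )
        } else {
          st <- pair_states(lags, i, j, config)
          suppressWarnings(filtered_gc(yi, st$restricted, st$full, config))
        }
        if (isTRUE(attr(d, "degenerate"))) degen[i, j] <- TRUE
        acc[i, j] <- acc[i, j] + as.numeric(d)
      }
    }
  }
  delta <- acc / length(eps_list)
  dimnames(delta) <- list(ep$montage$label, ep$montage$label)
  connectivity_matrix(
    delta = delta, band = ep$band, subject_id = ep$subject_id,
    group = ep$group, condition = ep$condition,
    n_epochs_used = length(eps_list), config = config, degenerate = degen
  )
}

#' Connectivity matrix container
#'
#' @param delta N x N matrix of filtered GC indices, `delta[i, j]` = flow
#'   from driver `j` to target `i`; zero diagonal.
#' @param band,subject_id,group,condition,n_epochs_used Provenance.
#' @param config The [gc_config] used.
#' @param sig_mask Optional logical N x N significance mask.
#' @param degenerate Optional logical N x N flag for numerically degenerate
#'   pairs (e.g. duplicate channels).
#' @return A `connectivity_matrix` with `delta`, `te` and `sig_mask` fields.
#' @export
connectivity_matrix <- function(delta, band = NULL, subject_id = NA_character_,
                                group = NA_character_, condition = NA_character_,
                                n_epochs_used = NA_integer_, config = NULL,
                                sig_mask = NULL, degenerate = NULL) {
  stopifnot(is.matrix(delta), nrow(delta) == ncol(delta))
  diag(delta) <- 0
  stopifnot(all(delta >= 0), all(delta < 1))
  if (is.null(sig_mask)) {
    sig_mask <- matrix(FALSE, nrow(delta), ncol(delta), dimnames = dimnames(delta))
  }
  diag(sig_mask) <- FALSE
  structure(
    list(
      delta = delta, te = transfer_entropy(delta), sig_mask = sig_mask,
      band = band, subject_id = subject_id, group = group,
      condition = condition, n_epochs_used = n_epochs_used, config = config,
      degenerate = degenerate
    ),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix %s/%s/%s%s: %d x %d, %d significant links, %d epochs>\n",
    x$subject_id, x$group, x$condition,
    if (is.null(x$band)) "" else paste0(" [", x$band$name, "]"),
    nrow(x$delta), ncol(x$delta), sum(x$sig_mask), x$n_epochs_used
  ))
  invisible(x)
}

#' Surrogate significance mask for a connectivity matrix
#'
#' For every ordered pair, a null distribution is built by circularly
#' time-shifting the driver channel by random offsets of at least `m`
#' samples and re-estimating the index; a link is significant when the
#' observed epoch-averaged `delta` exceeds the `1 - alpha` quantile of its
#' surrogate distribution. Reproducible for a fixed seed.
#'
#' @param cm A `connectivity_matrix` from [gc_matrix].
#' @param ep The `epoch_set` it was estimated from.
#' @param n_surrogates Number of surrogates; must satisfy
#'   `(n_surrogates + 1) * alpha >= 1` (19 for alpha = 0.05).
#' @param alpha Per-link level (default 0.05).
#' @param seed Integer seed.
#' @return The `connectivity_matrix` with `sig_mask` filled in.
#' @export
significance_mask <- function(cm, ep, n_surrogates = 99, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(cm, "connectivity_matrix"), inherits(ep, "epoch_set"))
  if ((n_surrogates + 1) * alpha < 1) {
    stop(sprintf(
      "%d surrogates cannot resolve alpha = %g (need >= %d)",
      n_surrogates, alpha, ceiling(1 / alpha) - 1
    ), call. = FALSE)
  }
  config <- cm$config %||% gc_config()
  eps_list <- retained_epochs(ep)
  n_ch <- nrow(cm$delta)
  m <- config$m
  n_ep <- length(eps_list)
  T_e <- ncol(eps_list[[1]])
  withr::with_seed(seed, {
    offsets <- matrix(
      sample(seq(m, T_e - m), n_surrogates * n_ep, replace = TRUE),
      n_surrogates, n_ep
    )
    # per-epoch embeddings; restricted bases/residuals cached per target
    emb <- lapply(eps_list, function(seg) {
      lapply(seq_len(n_ch), function(c) embed_series(seg[c, ], m))
    })
    fast <- use_fast_path(config)
    surro <- array(0, dim = c(n_ch, n_ch, n_surrogates))
    for (epi in seq_len(n_ep)) {
      lags <- lapply(emb[[epi]], `[[`, "states")
      caches <- if (fast) {
        lapply(seq_len(n_ch), function(i) {
          target_cache(emb[[epi]][[i]]$target, lags[[i]], config)
        })
      }
      linear <- fast && config$kernel == "linear"
      for (s in seq_len(n_surrogates)) {
        off <- offsets[s, epi]
        for (j in seq_len(n_ch)) {
          shifted <- embed_series(
            circ_shift(eps_list[[epi]][j, ], off), m
          )$states
          U_e <- if (linear) column_basis(shifted, config$eigenvalue_floor)
          for (i in seq_len(n_ch)) {
            if (i == j) next
            d <- if (fast) {
              gc_from_cache(caches[[i]], shifted, config, U_e = U_e)
            } else {
              lags_s <- lags
              lags_s[[j]] <- shifted
              st <- pair_states(lags_s, i, j, config)
              suppressWarnings(
                filtered_gc(emb[[epi]][[i]]$target, st$restricted, st$full, config)
              )
            }
            surro[i, j, s] <- surro[i, j, s] + as.numeric(d) / n_ep
          }
        }
      }
    }
  })
  qs <- apply(surro, c(1, 2), stats::quantile, probs = 1 - alpha, names = FALSE)
  mask <- cm$delta > qs
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(cm$delta)
  cm$sig_mask <- mask
  cm$surrogate_quantile <- qs
  cm
}

circ_shift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) x else c(x[(k + 1):n], x[1:k])
}

#' Write / read a connectivity matrix as TSV + JSON sidecar
#'
#' Matrices are written row = target, column = driver.
#'
#' @param cm A `connectivity_matrix`.
#' @param dir Output directory.
#' @param stem File stem; defaults to subject_condition_band.
#' @return Invisibly, the file paths.
#' @export
write_connectivity <- function(cm, dir, stem = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(stem)) {
    stem <- paste(cm$subject_id, gsub("[^A-Za-z0-9.]+", "-", cm$condition),
      if (is.null(cm$band)) "broadband" else cm$band$name,
      sep = "_"
    )
  }
  paths <- c(
    delta = file.path(dir, paste0(stem, "_delta.tsv")),
    te = file.path(dir, paste0(stem, "_te.tsv")),
    mask = file.path(dir, paste0(stem, "_mask.tsv")),
    meta = file.path(dir, paste0(stem, "_meta.json"))
  )
  write_matrix_tsv(cm$delta, paths["delta"])
  write_matrix_tsv(cm$te, paths["te"])
  write_matrix_tsv(cm$sig_mask * 1L, paths["mask"])
  meta <- list(
    subject = cm$subject_id, group = cm$group, condition = cm$condition,
    band = if (is.null(cm$band)) "broadband" else unclass(cm$band),
    n_epochs_used = cm$n_epochs_used,
    orientation = "row = target, column = driver",
    config = if (is.null(cm$config)) NULL else unclass(cm$config)
  )
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, null = "null")
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = TRUE,
    col.names = NA)
  invisible(path)
}
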