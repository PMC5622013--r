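# Independent oracles, deliberately naive: ordinary-least-squares Granger
# regression, exhaustive graph enumeration, histogram transfer entropy.
# They share no code with the package implementation.

# OLS Granger variance-ratio: (RSS_restricted - RSS_full) / RSS_restricted
ols_granger_oracle <- function(target, restricted, full) {
  fr <- stats::lm.fit(cbind(1, restricted), target)
  ff <- stats::lm.fit(cbind(1, full), target)
  rss_r <- sum(fr$residuals^2)
  rss_f <- sum(ff$residuals^2)
  (rss_r - rss_f) / rss_r
}

# Floyd-Warshall on 1/weight lengths; D[i, j] = distance i -> j where
# A[i, j] = weight of edge i -> j
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1 / A[A > 0]
  diag(D) <- 0
  for (k in 1:n) {
    for (i in 1:n) {
      for (j in 1:n) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_lambda <- function(A) {
  D <- bf_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

bf_efficiency <- function(A) {
  D <- bf_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (nrow(A) * (nrow(A) - 1))
}

# all shortest paths i -> j by exhaustive DFS over simple paths
bf_all_shortest_paths <- function(A, i, j) {
  n <- nrow(A)
  best <- list(len = Inf, paths = list())
  recurse <- function(node, visited, len, path) {
    if (len > best$len + 1e-12) return()
    if (node == j) {
      if (len < best$len - 1e-12) {
        best$len <<- len
        best$paths <<- list(path)
      } else {
        best$paths <<- c(best$paths, list(path))
      }
      return()
    }
    for (nxt in seq_len(n)) {
      if (A[node, nxt] > 0 && !(nxt %in% visited)) {
        recurse(nxt, c(visited, nxt), len + 1 / A[node, nxt], c(path, nxt))
      }
    }
  }
  recurse(i, i, 0, i)
  best
}

# vertex and edge betweenness by path enumeration (endpoints excluded)
bf_betweenness <- function(A) {
  n <- nrow(A)
  vbc <- numeric(n)
  ebc <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      sp <- bf_all_shortest_paths(A, i, j)
      np <- length(sp$paths)
      if (np == 0 || !is.finite(sp$len)) next
      for (p in sp$paths) {
        if (length(p) > 2) {
          for (mid in p[2:(length(p) - 1)]) vbc[mid] <- vbc[mid] + 1 / np
        }
        for (k in seq_len(length(p) - 1)) {
          ebc[p[k], p[k + 1]] <- ebc[p[k], p[k + 1]] + 1 / np
        }
      }
    }
  }
  list(vbc = vbc, ebc = ebc)
}

# Fagiolo directed weighted clustering by explicit triangle loops
bf_clustering <- function(A) {
  n <- nrow(A)
  W <- if (max(A) > 0) (A / max(A))^(1 / 3) else A
  bin <- (A > 0) * 1
  cc <- numeric(n)
  S <- W + t(W)
  for (i in 1:n) {
    # ((W^(1/3) + t(W)^(1/3))^3)_ii / 2 by explicit loops
    tri <- 0
    for (j in 1:n) {
      for (k in 1:n) tri <- tri + S[i, j] * S[j, k] * S[k, i]
    }
    tri <- tri / 2
    d_tot <- sum(bin[i, ] > 0) + sum(bin[, i] > 0)
    d_bi <- sum(bin[i, ] * bin[, i])
    denom <- d_tot * (d_tot - 1) - 2 * d_bi
    cc[i] <- if (denom > 0) tri / denom else 0
  }
  cc
}

# random weighted digraph adjacency, A[i, j] = weight of edge i -> j
random_digraph <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n), n, n) < p)
    diag(A) <- 0
    A
  })
}

# histogram (binned plug-in) transfer entropy oracle for a lag-1 pair:
# TE(y -> x) = sum p(x', x, y) log [ p(x'|x, y) / p(x'|x) ]
hist_te_oracle <- function(x, y, n_bins = 8) {
  T <- length(x)
  disc <- function(v) {
    cut(v, breaks = stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)),
      include.lowest = TRUE, labels = FALSE)
  }
  xp <- disc(x[2:T])
  xc <- disc(x[1:(T - 1)])
  yc <- disc(y[1:(T - 1)])
  p3 <- table(xp, xc, yc) / (T - 1)
  p_xcyc <- table(xc, yc) / (T - 1)
  p_xpxc <- table(xp, xc) / (T - 1)
  p_xc <- table(xc) / (T - 1)
  te <- 0
  for (a in 1:n_bins) {
    for (b in 1:n_bins) {
      for (c in 1:n_bins) {
        pj <- p3[a, b, c]
        if (pj > 0) {
          te <- te + pj * log(pj * p_xc[b] / (p_xcyc[b, c] * p_xpxc[a, b]))
        }
      }
    }
  }
  as.numeric(te)
}

# small single-group cohort spec used across tests
test_cohort_spec <- function(n_channels = 8, duration_s = 16, n_subjects = 1,
                             base_n_edges = 0, seed = 11, ...) {
  cohort_spec(
    groups = list(A = list(n_subjects = n_subjects, add = list(), coupling_scale = 1)),
    conditions = list(rest = list()),
    n_channels = n_channels, duration_s = duration_s,
    base_n_edges = base_n_edges, seed = seed, ...
  )
}

# epoch_set wrapper over a raw channels x samples matrix, split into epochs
epoch_set_from_matrix <- function(X, fs = 256, epoch_len = ncol(X)) {
  n_ep <- floor(ncol(X) / epoch_len)
  arr <- array(0, dim = c(n_ep, nrow(X), epoch_len))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- X[, ((e - 1) * epoch_len + 1):(e * epoch_len)]
  }
  structure(
    list(
      data = arr, eog = NULL, retained = rep(TRUE, n_ep), band = NULL,
      fs = fs, montage = tibble::tibble(label = paste0("n", seq_len(nrow(X)))),
      subject_id = "X", group = "X", condition = "X",
      rejection_log = tibble::tibble(epoch = integer(), reason = character())
    ),
    class = "epoch_set"
  )
}

# recording from an explicit edge list on the test spec
recording_from_edges <- function(edges, spec, subject_seed = 1) {
  tr <- ground_truth(spec$n_channels, edges)
  simulate_recording(tr, spec, subject_seed)
}
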