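#' Build a directed information network
#'
#' Turns a connectivity matrix into a directed weighted graph on the
#' electrodes. Weights are the chosen index (`delta` or `te`); entries whose
#' significance mask is `FALSE` are zeroed when the mask is applied, and a
#' zero weight means no edge.
#'
#' @param cm A `connectivity_matrix`.
#' @param weight_source "delta" or "te".
#' @param apply_mask Zero out non-significant links (default `TRUE`).
#' @param normalise Divide weights by their maximum so they lie in `[0, 1]`.
#' @return An `info_network`: `weights` (N x N, `weights[i, j]` = flow
#'   j -> i), `nodes`, `zone_map`, provenance labels and an `empty` flag.
#' @export
build_network <- function(cm, weight_source = c("delta", "te"),
                          apply_mask = TRUE, normalise = FALSE) {
  weight_source <- match.arg(weight_source)
  w <- cm[[weight_source]]
  if (apply_mask) w[!cm$sig_mask] <- 0
  diag(w) <- 0
  if (normalise && max(w) > 0) w <- w / max(w)
  info_network(
    weights = w, nodes = rownames(cm$delta),
    subject_id = cm$subject_id, group = cm$group, condition = cm$condition,
    band = cm$band
  )
}

#' @rdname build_network
#' @param weights Nonnegative N x N matrix, zero diagonal.
#' @param nodes Node (electrode) labels.
#' @param zone_map Optional named character vector label -> zone; derived
#'   from the labels when omitted.
#' @param subject_id,group,condition,band Provenance.
#' @export
info_network <- function(weights, nodes = rownames(weights), zone_map = NULL,
                         subject_id = NA_character_, group = NA_character_,
                         condition = NA_character_, band = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights), all(weights >= 0))
  diag(weights) <- 0
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(weights)))
  dimnames(weights) <- list(nodes, nodes)
  if (is.null(zone_map)) {
    zone_map <- tryCatch(
      stats::setNames(vapply(nodes, electrode_zone, character(1)), nodes),
      error = function(e) NULL
    )
  }
  structure(
    list(
      weights = weights, nodes = nodes, zone_map = zone_map, directed = TRUE,
      empty = all(weights == 0), subject_id = subject_id, group = group,
      condition = condition, band = band
    ),
    class = "info_network"
  )
}

#' @export
print.info_network <- function(x, ...) {
  cat(sprintf(
    "<info_network: %d nodes, %d directed edges%s>\n",
    length(x$nodes), sum(x$weights > 0), if (x$empty) " (empty)" else ""
  ))
  invisible(x)
}

# igraph view: edge i->j in igraph means flow i->j, so the weight matrix is
# transposed (weights[i, j] is j -> i). Edge attribute "weight" holds the
# information weight; metric functions pass 1/weight as the length.
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(t(net$weights),
    mode = "directed", weighted = TRUE
  )
}

edge_lengths <- function(g) 1 / igraph::E(g)$weight

# directed distance matrix on 1/weight lengths, D[i, j] = distance i -> j
distance_matrix <- function(net) {
  g <- as_igraph(net)
  igraph::distances(g, mode = "out", weights = edge_lengths(g))
}

#' Integration metrics: characteristic path length, eccentricity, diameter
#'
#' Edge lengths are the reciprocal of the information weight (a strong link
#' is a short path). `lambda` is the mean of all finite directed pairwise
#' distances; a node's eccentricity is its largest finite distance to any
#' other node; the diameter is the largest eccentricity. Unreachable pairs
#' are excluded from the means and reported as `disconnected_fraction`.
#'
#' @param net An `info_network`.
#' @return List with `lambda`, `eccentricity` (named vector), `diameter`,
#'   `disconnected_fraction`.
#' @export
path_metrics <- function(net) {
  D <- distance_matrix(net)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  if (!any(finite)) {
    stop("fully disconnected network: path length undefined", call. = FALSE)
  }
  ecc <- apply(D, 1, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) NA_real_ else max(d)
  })
  list(
    lambda = mean(off[finite]),
    eccentricity = ecc,
    diameter = max(ecc, na.rm = TRUE),
    disconnected_fraction = mean(!finite)
  )
}

#' Global and zone-wise efficiency
#'
#' Efficiency is the mean inverse shortest-path distance over ordered node
#' pairs, with unreachable pairs contributing zero — robust to
#' disconnection. The zone matrix restricts the average to source-zone ->
#' target-zone pairs (frontal, central, temporal, parietal, occipital;
#' optionally split by hemisphere).
#'
#' @param net An `info_network` with a zone map (for the zone matrix).
#' @param by_zone Compute the zone x zone matrix (default `TRUE` when a zone
#'   map is available).
#' @param split_side Split sided zones into left/right (midline electrodes
#'   keep their own stratum).
#' @return List with `global` and (optionally) `zones` (zone x zone matrix,
#'   rows = source zone, columns = target zone).
#' @export
global_efficiency <- function(net, by_zone = !is.null(net$zone_map),
                              split_side = FALSE) {
  D <- distance_matrix(net)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(D)
  out <- list(global = sum(inv) / (n * (n - 1)))
  if (by_zone) {
    if (is.null(net$zone_map)) stop("network has no zone map", call. = FALSE)
    zones <- net$zone_map[net$nodes]
    if (any(is.na(zones))) stop("unknown zone label for some nodes", call. = FALSE)
    if (split_side) {
      sides <- vapply(net$nodes, electrode_side, character(1))
      zones <- paste(zones, substr(sides, 1, 1), sep = "_")
    }
    lev <- unique(zones)
    zm <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
    # D[i, j] is distance i -> j; source zone indexes rows
    for (a in lev) {
      for (b in lev) {
        ia <- which(zones == a)
        ib <- which(zones == b)
        pairs <- expand.grid(ia, ib)
        pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
        zm[a, b] <- if (nrow(pairs) == 0) NA_real_ else {
          mean(inv[cbind(pairs[, 1], pairs[, 2])])
        }
      }
    }
    out$zones <- zm
  }
  out
}

#' Directed weighted clustering coefficient
#'
#' The geometric-mean formulation for weighted directed graphs: with
#' `W' = (W / max(W))^(1/3)` on the driver -> target orientation, the
#' coefficient of node `i` is `(W' + W'^T)^3_{ii} / 2` divided by the number
#' of possible directed triangles `d_tot (d_tot - 1) - 2 d_bidir`. Nodes
#' that cannot close a triangle (fewer than two neighbours) get 0.
#'
#' @param net An `info_network`.
#' @return Named per-node coefficient vector in `[0, 1]`.
#' @export
clustering_coef <- function(net) {
  A <- t(net$weights) # A[i, j] = flow i -> j
  if (max(A) > 0) A <- A / max(A)
  W <- A^(1 / 3)
  S <- W + t(W)
  num <- diag(S %*% S %*% S) / 2
  bin <- (A > 0) * 1
  d_tot <- rowSums(bin) + colSums(bin)
  d_bi <- diag(bin %*% bin)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  cc <- ifelse(denom > 0, num / denom, 0)
  stats::setNames(cc, net$nodes)
}

#' Betweenness centrality (vertex and edge variants)
#'
#' Shortest-path betweenness on 1/weight edge lengths, with fractional
#' credit for tied shortest paths; path endpoints are excluded from the
#' vertex variant.
#'
#' @param net An `info_network`.
#' @return List with `vbc` (named per-node vector) and `ebc` (tibble
#'   `source`, `target`, `weight`, `ebc`).
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  len <- edge_lengths(g)
  vbc <- igraph::betweenness(g, directed = TRUE, weights = len)
  eb <- igraph::edge_betweenness(g, directed = TRUE, weights = len)
  el <- igraph::as_edgelist(g)
  list(
    vbc = stats::setNames(as.numeric(vbc), net$nodes),
    ebc = tibble::tibble(
      source = el[, 1], target = el[, 2],
      weight = igraph::E(g)$weight, ebc = as.numeric(eb)
    )
  )
}

#' Degree assortativity over directed edges
#'
#' Pearson correlation between the out-degree of each edge's source and the
#' in-degree of its target — the resilience-class summary: disassortative
#' networks (hub-and-spoke) lose integration quickly when hubs fail.
#' Degenerate degree sequences (zero variance on either side) have no
#' defined correlation and return `NA` with a note.
#'
#' @param net An `info_network` with at least 2 edges.
#' @return Scalar in `[-1, 1]`, or `NA` with attribute `note`.
#' @export
assortativity_degree_dir <- function(net) {
  A <- (t(net$weights) > 0) * 1 # A[i, j] = edge i -> j
  edges <- which(A == 1, arr.ind = TRUE)
  if (nrow(edges) < 2) stop("need at least 2 edges", call. = FALSE)
  outd <- rowSums(A)
  ind <- colSums(A)
  xs <- outd[edges[, 1]]
  ys <- ind[edges[, 2]]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(structure(NA_real_, note = "degenerate: zero degree variance"))
  }
  stats::cor(xs, ys)
}

#' Targeted-attack resilience curve
#'
#' Removes nodes in decreasing out+in strength order and records the global
#' efficiency after each removal, normalised by the intact value.
#'
#' @param net An `info_network`.
#' @param steps Number of removals (default: half the nodes).
#' @return Tibble with `removed`, `node`, `efficiency`, `relative`.
#' @export
attack_resilience <- function(net, steps = floor(length(net$nodes) / 2)) {
  e0 <- global_efficiency(net, by_zone = FALSE)$global
  strength <- rowSums(net$weights) + colSums(net$weights)
  order_idx <- order(strength, decreasing = TRUE)
  rows <- vector("list", steps)
  w <- net$weights
  for (k in seq_len(steps)) {
    idx <- order_idx[k]
    w[idx, ] <- 0
    w[, idx] <- 0
    sub <- info_network(w, nodes = net$nodes, zone_map = net$zone_map)
    ek <- if (sub$empty) 0 else global_efficiency(sub, by_zone = FALSE)$global
    rows[[k]] <- tibble::tibble(
      removed = k, node = net$nodes[idx], efficiency = ek,
      relative = if (e0 > 0) ek / e0 else NA_real_
    )
  }
  dplyr::bind_rows(rows)
}

#' Degree-preserving null ensemble and z-scores
#'
#' Generates surrogate networks by pairwise directed edge swaps that
#' preserve every node's in- and out-degree exactly, shuffles the observed
#' weights onto the rewired edges, recomputes the scalar network features on
#' each surrogate, and z-scores the observed features against the ensemble.
#'
#' @param net An `info_network` with at least 2 edges.
#' @param n_surrogates Ensemble size (default 100).
#' @param rewires_per_edge Swap attempts per edge (default 10).
#' @param seed Integer seed; ensembles are reproducible per seed.
#' @return List with `z` (named vector), `observed`, `ensemble` (tibble,
#'   one row per surrogate) and `surrogates` (list of weight matrices).
#' @export
null_ensemble <- function(net, n_surrogates = 100, rewires_per_edge = 10,
                          seed = 1L) {
  n_edges <- sum(net$weights > 0)
  if (n_edges < 2) stop("graph too sparse to rewire", call. = FALSE)
  g0 <- as_igraph(net)
  wts <- igraph::E(g0)$weight
  observed <- scalar_features(net)
  rows <- vector("list", n_surrogates)
  mats <- vector("list", n_surrogates)
  withr::with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      gs <- igraph::rewire(
        g0, igraph::keeping_degseq(loops = FALSE, niter = rewires_per_edge * n_edges)
      )
      igraph::E(gs)$weight <- sample(wts)
      A <- as.matrix(igraph::as_adjacency_matrix(gs, attr = "weight", sparse = FALSE))
      sn <- info_network(t(A), nodes = net$nodes, zone_map = net$zone_map)
      mats[[s]] <- sn$weights
      rows[[s]] <- scalar_features(sn)
    }
  })
  ens <- dplyr::bind_rows(rows)
  mu <- vapply(ens, mean, numeric(1))
  sdv <- vapply(ens, stats::sd, numeric(1))
  z <- (unlist(observed) - mu) / sdv
  list(
    z = z, observed = tibble::as_tibble(observed), ensemble = ens,
    surrogates = mats
  )
}

# scalar feature vector used for null-model comparison
scalar_features <- function(net) {
  pm <- tryCatch(path_metrics(net), error = function(e) {
    list(lambda = NA_real_, diameter = NA_real_)
  })
  eff <- global_efficiency(net, by_zone = FALSE)$global
  cc <- mean(clustering_coef(net))
  assort <- tryCatch(as.numeric(assortativity_degree_dir(net)),
    error = function(e) NA_real_
  )
  tibble::tibble(
    lambda = pm$lambda, diameter = pm$diameter, efficiency = eff,
    clustering = cc, assortativity = assort
  )
}

#' All network features for one network
#'
#' Computes the four feature classes — integration (lambda, eccentricity,
#' diameter), segregation (clustering), centrality (vertex and edge
#' betweenness) and resilience (assortativity, attack curve) — and, when a
#' null ensemble is requested, z-scores of the scalar features against the
#' degree-preserving null.
#'
#' @param net An `info_network`.
#' @param null Result of [null_ensemble], `TRUE` to compute one with
#'   defaults, or `NULL` to skip.
#' @param seed Seed forwarded to [null_ensemble].
#' @return A `network_features` list: `scalars` tibble (feature, value,
#'   null_z), `per_node` tibble, `ebc` tibble, `zone_efficiency` matrix.
#' @export
network_features <- function(net, null = NULL, seed = 1L) {
  pm <- path_metrics(net)
  eff <- global_efficiency(net)
  cc <- clustering_coef(net)
  bc <- betweenness_centrality(net)
  assort <- tryCatch(assortativity_degree_dir(net), error = function(e) NA_real_)
  if (isTRUE(null)) null <- null_ensemble(net, seed = seed)
  scal <- tibble::tibble(
    feature = c("lambda", "diameter", "efficiency", "clustering", "assortativity"),
    value = c(pm$lambda, pm$diameter, eff$global, mean(cc), as.numeric(assort))
  )
  scal$null_z <- if (!is.null(null)) null$z[scal$feature] else NA_real_
  per_node <- tibble::tibble(
    node = net$nodes,
    zone = if (is.null(net$zone_map)) NA_character_ else unname(net$zone_map[net$nodes]),
    eccentricity = unname(pm$eccentricity[net$nodes]),
    clustering = unname(cc[net$nodes]),
    vbc = unname(bc$vbc[net$nodes]),
    in_strength = unname(rowSums(net$weights)[net$nodes]),
    out_strength = unname(colSums(net$weights)[net$nodes])
  )
  structure(
    list(
      scalars = scal, per_node = per_node, ebc = bc$ebc,
      zone_efficiency = eff$zones,
      disconnected_fraction = pm$disconnected_fraction,
      conventions = c(
        length = "edge length = 1 / weight",
        lambda = "mean over finite directed pairwise distances",
        efficiency = "unreachable pairs count as zero"
      ),
      subject_id = net$subject_id, group = net$group,
      condition = net$condition, band = net$band
    ),
    class = "network_features"
  )
}

#' @export
print.network_features <- function(x, ...) {
  cat("<network_features>\n")
  print(x$scalars)
  invisible(x)
}

#' Export a network as a weighted edge list
#'
#' @param net An `info_network`.
#' @param path Optional TSV output path.
#' @return Tibble `source`, `target`, `weight` (flow source -> target).
#' @export
as_edge_list <- function(net, path = NULL) {
  idx <- which(t(net$weights) > 0, arr.ind = TRUE)
  el <- tibble::tibble(
    source = net$nodes[idx[, 1]], target = net$nodes[idx[, 2]],
    weight = t(net$weights)[idx]
  )
  if (!is.null(path)) readr::write_tsv(el, path, progress = FALSE)
  el
}
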