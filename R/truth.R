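#' Ground-truth directed coupling graphs
#'
#' A ground-truth graph records which directed couplings a synthetic recording
#' was generated with, so that connectivity estimates can be scored against a
#' known answer. Edges carry a dimensionless coupling strength and are either
#' `linear` or `quadratic` (the quadratic option produces couplings invisible
#' to a purely linear detector).
#'
#' @param n_nodes Number of nodes (channels).
#' @param edges Tibble with columns `source`, `target` (1-based node indices),
#'   `strength`, `nonlinearity`.
#' @param seed Integer seed the graph was drawn with (provenance).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(n_nodes, edges, seed = NA_integer_) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(
      all(edges$source != edges$target),
      all(is.finite(edges$strength)),
      all(edges$nonlinearity %in% c("linear", "quadratic")),
      all(edges$source >= 1), all(edges$target <= n_nodes)
    )
    if (anyDuplicated(edges[, c("source", "target")]) > 0) {
      stop("duplicate edges in ground truth", call. = FALSE)
    }
  }
  structure(
    list(n_nodes = n_nodes, edges = edges, seed = seed),
    class = "ground_truth"
  )
}

#' @export
format.ground_truth <- function(x, ...) {
  sprintf("<ground_truth: %d nodes, %d directed edges>", x$n_nodes, nrow(x$edges))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(format(x), "\n")
  if (nrow(x$edges) > 0) print(x$edges, n = 10)
  invisible(x)
}

#' Draw a random ground-truth coupling graph
#'
#' Draws `n_edges` distinct directed edges (no self-loops). The `motif`
#' argument constrains edge placement to emulate the spatial patterns seen in
#' visual-stimulation EEG studies: `posterior_to_frontal` places sources in
#' parietal/occipital zones and targets in frontal/central zones (information
#' flow toward fronto-central regions under stimulation);
#' `posterior_cluster` confines both endpoints to parietal/occipital zones
#' (a segregated posterior cluster of connections).
#'
#' @param n_nodes Number of nodes; must equal `nrow(montage)` when a montage
#'   is supplied.
#' @param n_edges Number of directed edges, at most `n_nodes * (n_nodes - 1)`.
#' @param motif One of "random", "posterior_cluster", "posterior_to_frontal".
#' @param seed Integer seed; identical seeds give identical graphs.
#' @param montage Montage tibble (required for the posterior motifs).
#' @param coupling Coupling strength given to every edge.
#' @param nonlinearity "linear" or "quadratic", recycled over edges.
#' @param acyclic Restrict edges to a feed-forward (low index to high index)
#'   orientation. An acyclic coupling pattern leaves the spectral radius of
#'   the simulated system untouched, so dense motifs can carry full-strength
#'   couplings without destabilising the resonator dynamics.
#' @return A [ground_truth] object.
#' @export
simulate_truth <- function(n_nodes, n_edges,
                           motif = c("random", "posterior_cluster", "posterior_to_frontal"),
                           seed = 1L, montage = NULL,
                           coupling = 0.4, nonlinearity = "linear",
                           acyclic = FALSE) {
  motif <- match.arg(motif)
  if (n_edges > n_nodes * (n_nodes - 1)) {
    stop("n_edges exceeds the number of possible directed edges", call. = FALSE)
  }
  if (motif != "random" && is.null(montage)) {
    if (n_nodes %in% c(4L, 8L, 16L, 62L)) montage <- make_montage(n_nodes)
    else stop("posterior motifs need a montage with zone labels", call. = FALSE)
  }
  if (!is.null(montage) && nrow(montage) != n_nodes) {
    stop("montage size does not match n_nodes", call. = FALSE)
  }
  sources <- targets <- seq_len(n_nodes)
  if (motif == "posterior_cluster") {
    post <- which(montage$zone %in% c("parietal", "occipital"))
    sources <- targets <- post
  } else if (motif == "posterior_to_frontal") {
    sources <- which(montage$zone %in% c("parietal", "occipital"))
    targets <- which(montage$zone %in% c("frontal", "central"))
  }
  pairs <- expand.grid(source = sources, target = targets)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  if (acyclic) pairs <- pairs[pairs$source < pairs$target, , drop = FALSE]
  if (n_edges > nrow(pairs)) {
    stop("n_edges exceeds the number of edges compatible with motif '",
      motif, "' (", nrow(pairs), ")",
      call. = FALSE
    )
  }
  idx <- withr::with_seed(seed, sample.int(nrow(pairs), n_edges))
  edges <- tibble::tibble(
    source = pairs$source[idx],
    target = pairs$target[idx],
    strength = rep_len(coupling, n_edges),
    nonlinearity = rep_len(nonlinearity, n_edges)
  )
  ground_truth(n_nodes, edges, seed = seed)
}

# merge two edge sets; later edges override earlier ones on the same pair
merge_truth <- function(a, b) {
  stopifnot(a$n_nodes == b$n_nodes)
  e <- dplyr::bind_rows(a$edges, b$edges)
  e <- e[!duplicated(e[, c("source", "target")], fromLast = TRUE), , drop = FALSE]
  ground_truth(a$n_nodes, e, seed = a$seed)
}
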