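#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a connectivity matrix into a long link table
#'
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @return Tibble: `target`, `driver`, `delta`, `te`, `significant`.
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  labels <- rownames(x$delta)
  grid <- expand.grid(
    target = labels, driver = labels,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  out <- tibble::as_tibble(grid)
  out$delta <- as.vector(x$delta)
  out$te <- as.vector(x$te)
  out$significant <- as.vector(x$sig_mask)
  out <- out[out$target != out$driver, ]
  out$subject <- x$subject_id
  out$group <- x$group
  out$condition <- x$condition
  out$band <- if (is.null(x$band)) NA_character_ else x$band$name
  out
}

#' @rdname tidy.connectivity_matrix
#' @export
glance.connectivity_matrix <- function(x, ...) {
  off <- x$delta[row(x$delta) != col(x$delta)]
  tibble::tibble(
    n_channels = nrow(x$delta),
    n_epochs_used = x$n_epochs_used,
    mean_delta = mean(off),
    max_delta = max(off),
    n_significant = sum(x$sig_mask),
    band = if (is.null(x$band)) NA_character_ else x$band$name
  )
}

#' Tidy network features into a long table
#'
#' @param x A `network_features` object.
#' @param ... Unused.
#' @return Long tibble `feature`, `node` (NA for scalars), `value`,
#'   `null_z`, plus provenance columns.
#' @export
tidy.network_features <- function(x, ...) {
  scalars <- dplyr::mutate(x$scalars, node = NA_character_)
  per_node <- tidyr::pivot_longer(
    x$per_node[, c("node", "eccentricity", "clustering", "vbc")],
    cols = -"node", names_to = "feature", values_to = "value"
  )
  per_node$null_z <- NA_real_
  out <- dplyr::bind_rows(scalars, per_node)
  out$subject <- x$subject_id
  out$group <- x$group
  out$condition <- x$condition
  out$band <- if (is.null(x$band)) NA_character_ else x$band$name
  out
}

#' @rdname tidy.network_features
#' @export
glance.network_features <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$scalars[, c("feature", "value")],
    names_from = "feature", values_from = "value"
  )
  wide$disconnected_fraction <- x$disconnected_fraction
  wide
}

#' @rdname tidy.connectivity_matrix
#' @export
tidy.epoch_set <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$retained),
    retained = x$retained,
    subject = x$subject_id, group = x$group, condition = x$condition,
    band = if (is.null(x$band)) NA_character_ else x$band$name
  )
}
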