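#' Multiple-comparison configuration for group maps
#'
#' The Bonferroni factor for comparing every pair of groups across the
#' stimulation conditions beyond baseline:
#' `b = n_group_couples * (n_stims - 1)`. With the standard three groups
#' (3 couples) and three conditions this gives `b = 3 * 2 = 6`, so the 0.05
#' two-tailed level is lowered to `0.05 / 6` (0.008 to printed precision),
#' i.e. 0.004 per tail for the alternating one-tailed tests.
#'
#' @param base_alpha Uncorrected two-tailed level (default 0.05).
#' @param n_group_couples Number of group pairs compared (default 3).
#' @param n_stims Number of stimulation conditions including rest
#'   (default 3).
#' @return A `stat_config` with `b`, `corrected_alpha_two_tailed` and
#'   `per_tail_alpha`.
#' @export
stat_config <- function(base_alpha = 0.05, n_group_couples = 3, n_stims = 3) {
  b <- n_group_couples * (n_stims - 1)
  stopifnot(b >= 1, base_alpha > 0, base_alpha < 1)
  structure(
    list(
      base_alpha = base_alpha, n_group_couples = n_group_couples,
      n_stims = n_stims, b = b,
      corrected_alpha_two_tailed = base_alpha / b,
      per_tail_alpha = base_alpha / b / 2
    ),
    class = "stat_config"
  )
}

#' @export
print.stat_config <- function(x, ...) {
  cat(sprintf(
    "<stat_config: b = %d, corrected two-tailed %.4g (%.3f), per tail %.4g (%.3f)>\n",
    x$b, x$corrected_alpha_two_tailed, round(x$corrected_alpha_two_tailed, 3),
    x$per_tail_alpha, round(x$per_tail_alpha, 3)
  ))
  invisible(x)
}

#' Per-electrode information-transfer counts
#'
#' Counts, for each subject, band and electrode, the significant links
#' entering ("in": true entries in the electrode's row, row = target) and
#' exiting ("out": true entries in its column, column = driver).
#'
#' @param masks Named list (by subject) of logical N x N significance masks,
#'   or of `connectivity_matrix` objects.
#' @param band Band label attached to the output.
#' @return Tidy tibble: `subject`, `electrode`, `band`, `direction`
#'   ("in"/"out"), `count`.
#' @export
transfer_counts <- function(masks, band = NA_character_) {
  if (length(masks) == 0) stop("no masks supplied", call. = FALSE)
  if (is.null(names(masks))) names(masks) <- paste0("S", seq_along(masks))
  dims <- NULL
  rows <- purrr::imap(masks, function(mk, subj) {
    if (inherits(mk, "connectivity_matrix")) {
      if (!is.na(mk$subject_id) && !is.null(mk$subject_id)) subj <- mk$subject_id
      if (!is.null(mk$band)) band <- mk$band$name
      mk <- mk$sig_mask
    }
    stopifnot(is.matrix(mk), nrow(mk) == ncol(mk))
    if (is.null(dims)) dims <<- dim(mk)
    if (!identical(dim(mk), dims)) stop("mask shape mismatch", call. = FALSE)
    labels <- rownames(mk) %||% paste0("e", seq_len(nrow(mk)))
    diag(mk) <- FALSE
    tibble::tibble(
      subject = subj,
      electrode = rep(labels, 2),
      band = band,
      direction = rep(c("in", "out"), each = nrow(mk)),
      count = unname(c(rowSums(mk), colSums(mk)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of a sample against a normal distribution with the
#' sample's own mean and standard deviation — the gate used before trusting
#' parametric group tests. Degenerate (zero-variance) samples are reported
#' as non-normal with a note rather than an error.
#'
#' @param sample Numeric vector, length >= 5.
#' @return List with `p_value`, `statistic`, `normal` (at the 0.05 gate) and
#'   `note`.
#' @export
ks_normality <- function(sample) {
  stopifnot(length(sample) >= 5)
  if (stats::sd(sample) == 0) {
    return(list(
      p_value = 0, statistic = NA_real_, normal = FALSE,
      note = "degenerate sample (zero variance)"
    ))
  }
  kt <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean(sample), stats::sd(sample))
  )
  list(
    p_value = unname(kt$p.value), statistic = unname(kt$statistic),
    normal = kt$p.value > 0.05, note = NA_character_
  )
}

# pooled-variance two-sample t statistic (classical Student)
pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    return(list(t = 0, df = na + nb - 2))
  }
  list(t = (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb)), df = na + nb - 2)
}

#' Group statistical probability map
#'
#' Compares two groups' per-electrode transfer counts (or any per-subject
#' per-electrode quantity) cell by cell with a Student t test evaluated on
#' both tails, each at the Bonferroni-corrected per-tail level — the
#' "alternating left and right" one-tailed scheme. The signed relative
#' percent difference, `100 * (meanA - meanB) / mean(meanA, meanB)`, drives
#' the hot/cold display convention: positive (hot) favours the first group.
#' The KS normality gate annotates each cell and a Wilcoxon rank-sum
#' fallback p-value is reported for non-normal cells (an extension, clearly
#' labelled, never used for the significance flag).
#'
#' @param countsA,countsB Tidy count tibbles from [transfer_counts] for the
#'   two groups (first group = "hot" reference).
#' @param config A [stat_config].
#' @param welch Use Welch's t instead of pooled-variance (default `FALSE`).
#' @param labels Length-2 group labels, defaults `c("A", "B")`.
#' @return A `stat_map` tibble: electrode, band, direction, means, t, df,
#'   one-tailed p for each tail, `significant`, `pct_diff`, `favored`,
#'   `ks_normal`, `p_ranksum`.
#' @export
group_map <- function(countsA, countsB, config = stat_config(), welch = FALSE,
                      labels = c("A", "B")) {
  check_counts <- function(x) {
    stopifnot(all(c("subject", "electrode", "direction", "count") %in% names(x)))
    if (dplyr::n_distinct(x$subject) < 2) {
      stop("need at least 2 subjects per group", call. = FALSE)
    }
    if (!"band" %in% names(x)) x$band <- NA_character_
    x
  }
  countsA <- check_counts(countsA)
  countsB <- check_counts(countsB)
  cells <- dplyr::distinct(
    dplyr::bind_rows(
      countsA[, c("electrode", "band", "direction")],
      countsB[, c("electrode", "band", "direction")]
    )
  )
  res <- purrr::pmap(cells, function(electrode, band, direction) {
    pick <- function(x) {
      x$count[x$electrode == electrode & x$direction == direction &
        (is.na(band) | x$band %in% band)]
    }
    a <- pick(countsA)
    b <- pick(countsB)
    if (welch) {
      tt <- stats::t.test(a, b)
      tv <- unname(tt$statistic)
      df <- unname(tt$parameter)
    } else {
      pt_ <- pooled_t(a, b)
      tv <- pt_$t
      df <- pt_$df
    }
    p_right <- stats::pt(tv, df, lower.tail = FALSE) # A > B tail
    p_left <- stats::pt(tv, df, lower.tail = TRUE) # A < B tail
    mm <- mean(c(mean(a), mean(b)))
    pct <- if (mm == 0) 0 else 100 * (mean(a) - mean(b)) / mm
    ksn <- if (stats::sd(c(a, b)) == 0 || length(c(a, b)) < 5) NA else {
      ks_normality(c(a - mean(a), b - mean(b)))$normal
    }
    p_rs <- if (stats::sd(c(a, b)) == 0) NA_real_ else {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    tibble::tibble(
      electrode = electrode, band = band, direction = direction,
      mean_a = mean(a), mean_b = mean(b), t = tv, df = df,
      p_right = p_right, p_left = p_left,
      significant = min(p_right, p_left) < config$per_tail_alpha,
      pct_diff = pct,
      favored = dplyr::case_when(
        tv > 0 ~ labels[1], tv < 0 ~ labels[2], TRUE ~ NA_character_
      ),
      ks_normal = ksn, p_ranksum = p_rs
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "config") <- config
  attr(out, "labels") <- labels
  attr(out, "tails") <- "both tails tested, each at per_tail_alpha"
  class(out) <- c("stat_map", class(out))
  out
}

#' One-way ANOVA over groups for scalar network features
#'
#' Fixed-effects one-way F test per feature across groups, Bonferroni
#' corrected over features with the same correction machinery as the maps.
#'
#' @param features Tidy tibble with columns `group`, `subject`, `feature`,
#'   `value` (e.g. stacked `scalars` from [network_features]).
#' @param config A [stat_config]; its `b` is replaced by the number of
#'   features for the across-feature correction.
#' @return Tibble: feature, F, df1, df2, p, p_bonf, significant.
#' @export
feature_anova <- function(features, config = stat_config()) {
  stopifnot(all(c("group", "feature", "value") %in% names(features)))
  n_groups <- dplyr::n_distinct(features$group)
  if (n_groups < 2) stop("need at least 2 groups", call. = FALSE)
  counts <- dplyr::count(features, .data$feature, .data$group)
  if (any(counts$n < 2)) stop("need at least 2 subjects per group", call. = FALSE)
  feats <- unique(features$feature)
  res <- purrr::map(feats, function(f) {
    d <- features[features$feature == f & is.finite(features$value), ]
    fit <- stats::aov(value ~ factor(group), data = d)
    s <- summary(fit)[[1]]
    tibble::tibble(
      feature = f, F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
      p = s$`Pr(>F)`[1]
    )
  })
  out <- dplyr::bind_rows(res)
  out$p_bonf <- pmin(out$p * length(feats), 1)
  out$significant <- out$p_bonf < config$base_alpha
  out
}
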