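default_pipeline_config <- function() {
  list(
    out_dir = "gcnet-output",
    seed = 1L,
    montage = 16,
    bands = list(alpha = c(8, 12)),
    epoch_length_s = 4,
    overlap = 0,
    artifact = list(amplitude_limit = 150, eog_correlation_limit = 0.7),
    gc = list(
      m = 5, kernel = "linear", degree = 2, alpha = 0.05,
      eigenvalue_floor = 1e-6, conditioning = "bivariate"
    ),
    surrogates = list(n = 19, alpha = 0.05),
    network = list(
      weight_source = "delta", normalise = FALSE,
      null_surrogates = 100, rewires_per_edge = 10
    ),
    stats = list(base_alpha = 0.05),
    cohort = list(
      groups = list(MA = 3, MO = 3, C = 3),
      conditions = c("rest", "stim_0.5cpd", "stim_2.0cpd"),
      duration_s = 20, fs = 256
    ),
    write_fixtures = FALSE
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in every documented default
#' (embedding order 5, 4 s epochs, 100 null-model surrogates, ...) and
#' collects all validation errors at once rather than failing on the first.
#'
#' @param x Path to a YAML config file, or a named list.
#' @return A normalised `pipeline_config` list; errors abort with the full
#'   list of problems.
#' @export
validate_pipeline_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  defaults <- default_pipeline_config()
  errors <- character(0)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, x[setdiff(names(x), unknown)])
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    errors <- c(errors, "seed must be a nonnegative integer")
  }
  if (!cfg$montage %in% c(4, 5, 8, 16, 62)) {
    errors <- c(errors, "montage must be one of 4, 5, 8, 16, 62")
  }
  for (bn in names(cfg$bands)) {
    b <- cfg$bands[[bn]]
    if (length(b) != 2 || !is.numeric(b) || b[1] <= 0 || b[1] >= b[2]) {
      errors <- c(errors, sprintf("band '%s' must be numeric c(low, high) with 0 < low < high", bn))
    } else if (b[2] >= cfg$cohort$fs / 2) {
      errors <- c(errors, sprintf("band '%s' exceeds the Nyquist frequency", bn))
    }
  }
  if (cfg$epoch_length_s <= 0) errors <- c(errors, "epoch_length_s must be positive")
  if (cfg$overlap < 0 || cfg$overlap >= 1) errors <- c(errors, "overlap must be in [0, 1)")
  if (cfg$gc$m < 1) errors <- c(errors, "gc$m must be >= 1")
  if (!cfg$gc$kernel %in% c("linear", "poly", "gaussian")) {
    errors <- c(errors, "gc$kernel must be linear, poly or gaussian")
  }
  if ((cfg$surrogates$n + 1) * cfg$surrogates$alpha < 1) {
    errors <- c(errors, "too few link surrogates for the requested alpha")
  }
  if (any(unlist(cfg$cohort$groups) < 1)) {
    errors <- c(errors, "every group needs at least 1 subject")
  }
  if (length(errors) > 0) {
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
      call. = FALSE
    )
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg, stage) {
  rlang::hash(list(stage = stage, cfg = unclass(cfg)))
}

stage_dir <- function(cfg, stage) file.path(cfg$out_dir, stage)

stage_done <- function(cfg, stage) {
  marker <- file.path(stage_dir(cfg, stage), ".stage.json")
  if (!file.exists(marker)) return(FALSE)
  info <- jsonlite::read_json(marker)
  identical(info$hash, config_hash(cfg, stage))
}

mark_stage <- function(cfg, stage, log) {
  jsonlite::write_json(
    list(
      stage = stage, hash = config_hash(cfg, stage),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), log = log
    ),
    file.path(stage_dir(cfg, stage), ".stage.json"),
    auto_unbox = TRUE
  )
}

load_state <- function(cfg, stage, what) {
  f <- file.path(stage_dir(cfg, stage), paste0(what, ".rds"))
  if (!file.exists(f)) {
    stop(sprintf(
      "stage '%s' needs output '%s' from an earlier stage; run that stage first",
      stage, what
    ), call. = FALSE)
  }
  readRDS(f)
}

save_state <- function(cfg, stage, what, value) {
  saveRDS(value, file.path(stage_dir(cfg, stage), paste0(what, ".rds")))
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> connect -> network -> stats ->
#' report over a deterministic artifact tree under `config$out_dir`. Each
#' stage writes its interchange files (TSV matrices and tables, JSON
#' provenance) plus an internal state file the next stage reads, and records
#' a hash of the configuration: re-running an unchanged stage is a no-op.
#'
#' @param config A `pipeline_config` (or anything [validate_pipeline_config]
#'   accepts).
#' @param stages Subset of
#'   `c("simulate", "preprocess", "connect", "network", "stats", "report")`.
#' @param force Re-run stages even when their hash is unchanged.
#' @return Invisibly, a tibble log (stage, status, seconds).
#' @export
run_pipeline <- function(config = list(),
                         stages = c(
                           "simulate", "preprocess", "connect",
                           "network", "stats", "report"
                         ),
                         force = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  log_rows <- list()
  run_stage <- function(stage, fn) {
    dir.create(stage_dir(cfg, stage), recursive = TRUE, showWarnings = FALSE)
    if (!force && stage_done(cfg, stage)) {
      message(sprintf("[%s] up to date, skipping", stage))
      log_rows[[stage]] <<- tibble::tibble(
        stage = stage, status = "skipped", seconds = 0
      )
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    detail <- fn()
    secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    mark_stage(cfg, stage, detail)
    message(sprintf("[%s] done in %.1f s", stage, secs))
    log_rows[[stage]] <<- tibble::tibble(
      stage = stage, status = "run", seconds = secs
    )
  }

  if ("simulate" %in% stages) run_stage("simulate", function() pipeline_simulate(cfg))
  if ("preprocess" %in% stages) run_stage("preprocess", function() pipeline_preprocess(cfg))
  if ("connect" %in% stages) run_stage("connect", function() pipeline_connect(cfg))
  if ("network" %in% stages) run_stage("network", function() pipeline_network(cfg))
  if ("stats" %in% stages) run_stage("stats", function() pipeline_stats(cfg))
  if ("report" %in% stages) run_stage("report", function() pipeline_report(cfg))
  invisible(dplyr::bind_rows(log_rows))
}

pipeline_cohort_spec <- function(cfg) {
  groups <- purrr::imap(cfg$cohort$groups, function(n, label) {
    g <- list(n_subjects = n, add = list(), coupling_scale = 1)
    if (label == "MA") {
      g$add <- list(list(
        motif = "posterior_cluster", n_edges = 6, coupling = 0.4,
        nonlinearity = "linear", stim_only = TRUE
      ))
    }
    if (label == "MO") g$coupling_scale <- 0.8
    g
  })
  conditions <- stats::setNames(
    lapply(cfg$cohort$conditions, function(cl) {
      if (identical(cl, "rest")) list() else {
        list(list(
          motif = "posterior_to_frontal", n_edges = 8,
          coupling = if (grepl("2", cl)) 0.45 else 0.4, nonlinearity = "linear"
        ))
      }
    }),
    cfg$cohort$conditions
  )
  cohort_spec(
    groups = groups, conditions = conditions, n_channels = cfg$montage,
    duration_s = cfg$cohort$duration_s, fs = cfg$cohort$fs, seed = cfg$seed
  )
}

pipeline_simulate <- function(cfg) {
  spec <- pipeline_cohort_spec(cfg)
  cohort <- simulate_cohort(spec)
  save_state(cfg, "simulate", "cohort", cohort)
  readr::write_tsv(cohort$manifest,
    file.path(stage_dir(cfg, "simulate"), "manifest.tsv"),
    progress = FALSE
  )
  if (isTRUE(cfg$write_fixtures)) {
    write_fixture(cohort, "txt", file.path(stage_dir(cfg, "simulate"), "fixtures"))
  }
  list(n_recordings = length(cohort$recordings))
}

pipeline_preprocess <- function(cfg) {
  cohort <- load_state(cfg, "simulate", "cohort")
  criteria <- artifact_criteria(
    cfg$artifact$amplitude_limit, cfg$artifact$eog_correlation_limit
  )
  epochs <- list()
  logs <- list()
  bands <- lapply(names(cfg$bands), function(bn) {
    band_spec(bn, cfg$bands[[bn]][1], cfg$bands[[bn]][2])
  })
  names(bands) <- names(cfg$bands)
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    eps <- preprocess_recording(
      rec, bands, cfg$epoch_length_s, cfg$overlap, criteria
    )
    for (bn in names(eps)) {
      ep <- eps[[bn]]
      epochs[[paste(key, bn, sep = "/")]] <- ep
      logs[[paste(key, bn, sep = "/")]] <- tibble::tibble(
        recording = key, band = bn,
        n_epochs = length(ep$retained), n_retained = sum(ep$retained)
      )
    }
  }
  save_state(cfg, "preprocess", "epochs", epochs)
  readr::write_tsv(dplyr::bind_rows(logs),
    file.path(stage_dir(cfg, "preprocess"), "retention.tsv"),
    progress = FALSE
  )
  list(n_epoch_sets = length(epochs))
}

pipeline_connect <- function(cfg) {
  epochs <- load_state(cfg, "preprocess", "epochs")
  gcc <- gc_config(
    m = cfg$gc$m, kernel = cfg$gc$kernel, degree = cfg$gc$degree,
    alpha = cfg$gc$alpha, eigenvalue_floor = cfg$gc$eigenvalue_floor,
    conditioning = cfg$gc$conditioning
  )
  cms <- purrr::imap(epochs, function(ep, key) {
    cm <- gc_matrix(ep, gcc)
    cm <- significance_mask(
      cm, ep,
      n_surrogates = cfg$surrogates$n, alpha = cfg$surrogates$alpha,
      seed = derive_seed(cfg$seed, nchar(key), sum(utf8ToInt(key)))
    )
    write_connectivity(cm, file.path(stage_dir(cfg, "connect"), "matrices"))
    cm
  })
  save_state(cfg, "connect", "matrices", cms)
  list(n_matrices = length(cms))
}

pipeline_network <- function(cfg) {
  cms <- load_state(cfg, "connect", "matrices")
  feats <- purrr::imap(cms, function(cm, key) {
    net <- build_network(
      cm, cfg$network$weight_source,
      apply_mask = TRUE, normalise = cfg$network$normalise
    )
    if (net$empty || sum(net$weights > 0) < 2) {
      return(NULL)
    }
    nf <- tryCatch(network_features(net), error = function(e) NULL)
    if (is.null(nf)) return(NULL)
    tidy(nf)
  })
  tbl <- dplyr::bind_rows(feats)
  save_state(cfg, "network", "features", tbl)
  readr::write_tsv(tbl, file.path(stage_dir(cfg, "network"), "features.tsv"),
    progress = FALSE
  )
  list(n_feature_rows = nrow(tbl))
}

pipeline_stats <- function(cfg) {
  cms <- load_state(cfg, "connect", "matrices")
  meta <- purrr::imap_dfr(cms, function(cm, key) {
    tibble::tibble(
      key = key, subject = cm$subject_id, group = cm$group,
      condition = cm$condition,
      band = if (is.null(cm$band)) "broadband" else cm$band$name
    )
  })
  groups <- unique(meta$group)
  conditions <- unique(meta$condition)
  config <- stat_config(
    base_alpha = cfg$stats$base_alpha,
    n_group_couples = max(1, choose(length(groups), 2)),
    n_stims = length(conditions)
  )
  counts_for <- function(grp, cond) {
    keys <- meta$key[meta$group == grp & meta$condition == cond]
    masks <- purrr::map(stats::setNames(keys, meta$subject[match(keys, meta$key)]),
      function(k) cms[[k]]
    )
    transfer_counts(masks)
  }
  maps <- list()
  couples <- utils::combn(groups, 2, simplify = FALSE)
  for (cond in conditions) {
    for (cp in couples) {
      ca <- counts_for(cp[1], cond)
      cb <- counts_for(cp[2], cond)
      if (dplyr::n_distinct(ca$subject) < 2 || dplyr::n_distinct(cb$subject) < 2) next
      sm <- group_map(ca, cb, config, labels = cp)
      sm$comparison <- paste(cp[1], "vs", cp[2])
      sm$condition <- cond
      maps[[paste(cond, cp[1], cp[2])]] <- sm
    }
  }
  # each stimulation condition against rest, within group
  if ("rest" %in% conditions) {
    for (grp in groups) {
      for (cond in setdiff(conditions, "rest")) {
        ca <- counts_for(grp, cond)
        cb <- counts_for(grp, "rest")
        if (dplyr::n_distinct(ca$subject) < 2) next
        sm <- group_map(ca, cb, config, labels = c(cond, "rest"))
        sm$comparison <- paste(grp, cond, "vs rest")
        sm$condition <- cond
        maps[[paste(grp, cond, "rest")]] <- sm
      }
    }
  }
  all_maps <- dplyr::bind_rows(purrr::map(maps, tibble::as_tibble))
  save_state(cfg, "stats", "maps", all_maps)
  readr::write_tsv(all_maps, file.path(stage_dir(cfg, "stats"), "stat_maps.tsv"),
    progress = FALSE
  )
  feats <- tryCatch(load_state(cfg, "network", "features"), error = function(e) NULL)
  if (!is.null(feats) && nrow(feats) > 0) {
    scalars <- feats[is.na(feats$node) & is.finite(feats$value), ]
    if (dplyr::n_distinct(scalars$group) >= 2) {
      anova_tbl <- feature_anova(
        scalars[, c("group", "subject", "feature", "value")], config
      )
      readr::write_tsv(anova_tbl,
        file.path(stage_dir(cfg, "stats"), "feature_anova.tsv"),
        progress = FALSE
      )
    }
  }
  list(n_maps = length(maps))
}

pipeline_report <- function(cfg) {
  files <- list.files(cfg$out_dir, recursive = TRUE)
  prov <- list(
    package = "gcnet",
    version = as.character(utils::packageVersion("gcnet")),
    r_version = R.version.string,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    files = files
  )
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  list(n_files = length(files))
}
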