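# Reproducible analysis runs: one entry point gluing I/O, simulation and
# the statistics together. Each run writes its results as CSV/JSON files
# plus a machine-readable manifest of the effective parameters, so a rerun
# from the manifest reproduces the outputs byte for byte.

PIPELINE_COMMANDS <- c("simulate", "validate", "classify", "growth",
                       "speed", "kinship", "msd", "proximity", "report")

#' Default analysis parameters
#'
#' The defaults of every tunable analysis parameter: 0.25 h (15 min)
#' smoothing bandwidth, 8 h power-mean window, lattice bandwidth 1.5 for
#' the descendant-count histogram, Scott's rule for the length KDE, 70 h /
#' 20 h descendant horizons, 60 h / 30 h track-length horizons, 4 h
#' minimum proximity duration with 2 h post-birth exclusion, and a
#' 100-root analysis frame.
#'
#' @return Named list of parameter defaults; any element can be overridden
#'   via the `params` entry of [run_pipeline()]'s config.
#' @export
default_params <- function() {
  list(bandwidth = 0.25,           # h, trajectory smoothing
       power_window = 8,           # h, moving power-mean window
       power_orders = c(1, 4),
       pair_bandwidth = 1.5,       # lattice units, descendant-count smoothing
       descendant_horizon = 70,    # h
       descendant_birth_window = 20,
       length_horizon = 60,        # h
       length_birth_window = 30,
       msd_t_max = 15,             # h
       msd_step = 0.5,
       msd_smoothing = TRUE,
       prox_threshold = 30,        # length units, ~one cell diameter
       prox_min_duration = 4,      # h
       prox_birth_exclusion = 2,   # h
       n_frame_roots = 100,
       grid_step = NULL)           # h, growth-curve grid (NULL: frame interval)
}

load_run_dataset <- function(config, seed) {
  if (!is.null(config$tracks)) {
    meta <- config$metadata %||% list()
    read_dataset(config$tracks, config$cells,
                 frame_interval_h = meta$frame_interval_h %||% 0.1,
                 duration_h = meta$duration_h %||% 94,
                 exposure = meta$exposure %||% "",
                 spatial_unit = meta$spatial_unit %||% "um")
  } else if (!is.null(config$sim)) {
    simulate_forest(do.call(sim_config, config$sim), seed = seed)
  } else {
    tf_error("tf_config_error",
             "config needs either input paths ('tracks'/'cells') or a 'sim' block")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline command
#'
#' Executes one of the package's analyses end to end — load or simulate a
#' dataset, run the statistic, write results and a manifest into `out` —
#' deterministically for a given config and seed. `report` runs every
#' analysis in sequence.
#'
#' @param command one of `"simulate"`, `"validate"`, `"classify"`,
#'   `"growth"`, `"speed"`, `"kinship"`, `"msd"`, `"proximity"`,
#'   `"report"`.
#' @param config list with optional entries `tracks`/`cells` (input CSV
#'   paths), `metadata` (frame interval, duration, exposure), `sim` (list
#'   of [sim_config()] arguments for synthetic input), `out` (output
#'   directory, default `"."`), `seed` (default 1) and `params` (overrides
#'   of [default_params()]).
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(command, config = list()) {
  if (!command %in% PIPELINE_COMMANDS)
    tf_error("tf_config_error", "unknown command '%s' (use one of: %s)",
             command, paste(PIPELINE_COMMANDS, collapse = ", "))
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  par <- utils::modifyList(default_params(), config$params %||% list())
  written <- character(0)
  emit <- function(name) written <<- c(written, file.path(out, name))

  ds <- load_run_dataset(config, seed)
  step <- par$grid_step %||% ds$metadata$frame_interval_h

  if (command %in% c("simulate", "report")) {
    write_dataset(ds, file.path(out, "tracks.csv"), file.path(out, "cells.csv"))
    emit("tracks.csv"); emit("cells.csv")
  }
  if (command %in% c("validate", "report")) {
    utils::write.csv(validate_dataset(ds), file.path(out, "validation.csv"),
                     row.names = FALSE)
    emit("validation.csv")
  }

  needs_forest <- command %in% c("classify", "growth", "kinship", "msd",
                                 "proximity", "report")
  if (needs_forest) {
    n_root_total <- sum(is.na(ds$cells$parent_id))
    roots <- if (n_root_total > par$n_frame_roots)
      select_root_frame(ds, par$n_frame_roots)$roots else NULL
    forest <- build_forest(ds, roots)
  }

  if (command %in% c("classify", "report")) {
    utils::write.csv(classify_trees(forest),
                     file.path(out, "classification.csv"), row.names = FALSE)
    emit("classification.csv")
  }
  if (command %in% c("growth", "report")) {
    for (sp in c("all", "no_death", "surviving")) {
      for (md in c("from_start", "post_first_division")) {
        cur <- tryCatch(
          population_growth_curve(forest, sp, md, step = step),
          tf_error = function(e) NULL)
        if (is.null(cur)) next
        f <- sprintf("growth_%s_%s.csv", sp, md)
        export_growth(cur, file.path(out, f)); emit(f)
        if (md == "from_start") {
          fj <- sprintf("growth_fit_%s.json", sp)
          export_growth(fit_growth_polynomial(cur), file.path(out, fj))
          emit(fj)
        }
      }
    }
  }
  if (command %in% c("speed", "report")) {
    for (p in par$power_orders) {
      sd_ <- speed_distribution(ds, p = p, window = par$power_window,
                                bandwidth = par$bandwidth)
      f <- sprintf("speed_bins_p%g.csv", p)
      utils::write.csv(sd_$bins, file.path(out, f), row.names = FALSE)
      emit(f)
    }
  }
  if (command %in% c("kinship", "report")) {
    dp <- sister_descendant_pairs(forest, par$descendant_horizon,
                                  par$descendant_birth_window)
    utils::write.csv(as.data.frame(dp), file.path(out, "descendant_pairs.csv"),
                     row.names = FALSE)
    emit("descendant_pairs.csv")
    lp <- subtree_length_pairs(forest, ds, par$length_horizon,
                               par$length_birth_window, par$bandwidth)
    utils::write.csv(as.data.frame(lp), file.path(out, "length_pairs.csv"),
                     row.names = FALSE)
    emit("length_pairs.csv")
    cors <- list(
      descendant_count = if (nrow(dp) >= 3)
        tryCatch(as.numeric(pair_correlation(dp)), tf_error = function(e) NA)
      else NA,
      subtree_length = if (nrow(lp) >= 3)
        tryCatch(as.numeric(pair_correlation(lp)), tf_error = function(e) NA)
      else NA)
    jsonlite::write_json(cors, file.path(out, "pair_correlations.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    emit("pair_correlations.json")
  }
  if (command %in% c("msd", "report")) {
    sis <- first_generation_sisters(forest)
    cohort <- c(sis$daughter1, sis$daughter2)
    if (length(cohort) > 0) {
      m <- msd_curves(ds, cohort, par$msd_t_max, par$msd_step,
                      par$bandwidth, par$msd_smoothing)
      cross <- sibling_cross_msd(ds, sis, par$msd_t_max, par$msd_step,
                                 par$bandwidth, par$msd_smoothing)
      tab <- merge(m$curve, cross[, c("t_h", "mean_c12_over_t", "n_pairs")],
                   by = "t_h")
      utils::write.csv(tab, file.path(out, "displacement_curves.csv"),
                       row.names = FALSE)
      emit("displacement_curves.csv")
      fit <- tryCatch(estimate_memory_time(m), tf_error = function(e) NULL)
      if (!is.null(fit)) {
        jsonlite::write_json(list(P_h = fit$P, D = fit$D, rss = fit$rss,
                                  censored = fit$censored),
                             file.path(out, "memory_time.json"),
                             auto_unbox = TRUE, digits = NA)
        emit("memory_time.json")
      }
    }
  }
  if (command %in% c("proximity", "report")) {
    ev <- detect_proximity_events(ds, par$prox_threshold,
                                  par$prox_min_duration,
                                  par$prox_birth_exclusion,
                                  bandwidth = par$bandwidth)
    utils::write.csv(as.data.frame(ev), file.path(out, "proximity_events.csv"),
                     row.names = FALSE)
    emit("proximity_events.csv")
  }

  manifest <- list(
    command = command,
    seed = seed,
    params = par,
    inputs = if (!is.null(config$tracks))
      as.list(tools::md5sum(c(config$tracks, config$cells))) else NULL,
    sim = config$sim,
    package = "trackforest",
    version = as.character(utils::packageVersion("trackforest")),
    outputs = basename(written))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  written <- c(written, file.path(out, "manifest.json"))
  invisible(written)
}
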