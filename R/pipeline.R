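#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on a synthetic study (or on supplied
#' inputs): interaction scoring, drifting times and distractor biases, SEI /
#' IEI weight grid searches per group and condition, image-withdrawal
#' robustness, the saline/OT condition contrast, and a run manifest. All
#' outputs are plain CSV/JSON and deterministic given inputs and seed.
#'
#' @param config a [study_config()], or the path of a YAML file whose keys are
#'   `study_config()` arguments; used to simulate when `events`/`trials` are
#'   not supplied.
#' @param seed integer seed for simulation.
#' @param out_dir output directory (created if missing).
#' @param events,trials optional pre-loaded inputs: an event log plus a single
#'   trial table (columns as in [validate_trials()]); when supplied, no
#'   simulation is run and conditions present in `trials$drug_condition` are
#'   analyzed.
#' @param grid_step weight grid step (default 0.02).
#' @param alpha significance level for the robustness stage (default 0.05).
#' @param stages character subset of
#'   `c("score", "bias", "fit", "robustness", "contrast")`.
#' @param write_surfaces also write dense r-surface CSVs (default FALSE).
#' @return invisible list with the computed objects and output paths.
#' @export
run_pipeline <- function(config = study_config(), seed = 1, out_dir = "results",
                         events = NULL, trials = NULL, grid_step = 0.02,
                         alpha = 0.05,
                         stages = c("score", "bias", "fit", "robustness", "contrast"),
                         write_surfaces = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    raw <- yaml::read_yaml(config)
    known <- intersect(names(raw), names(formals(study_config)))
    unknown <- setdiff(names(raw), known)
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    config <- do.call(study_config, lapply(raw[known], function(v) {
      if (is.list(v)) if (all(lengths(v) == 1) && !is.null(names(v))) unlist(v) else v else v
    }))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  simulated <- is.null(events) || is.null(trials)
  if (simulated) {
    bundle <- gen_full_study(config, seed)
    events <- bundle$events
    trials <- rbind(bundle$trials_saline, bundle$trials_ot)
    roster <- config$roster
  } else {
    bundle <- NULL
    roster <- sort(unique(c(events$actor, events$recipient)))
  }
  validate_trials(trials)

  matrices <- build_score_matrices(events, roster)
  results <- list(matrices = matrices)
  if ("score" %in% stages) {
    paths$events <- file.path(out_dir, "events.csv")
    write_events_csv(events, paths$events)
    for (d in SOC_DIMENSIONS) {
      p <- file.path(out_dir, sprintf("score_matrix_%s.csv", d))
      write_score_matrix(matrices[[d]], p)
      paths[[paste0("score_", d)]] <- p
    }
    paths$trials <- file.path(out_dir, "trials.csv")
    write_trials_csv(trials, paths$trials)
  }

  conditions <- unique(trials$drug_condition)
  per_cond <- list()
  for (cond in conditions) {
    tc <- trials[trials$drug_condition == cond, , drop = FALSE]
    dt <- drifting_time_table(tc)
    res <- list(dt = dt)
    if ("bias" %in% stages) {
      for (g in c("in", "out", "all")) {
        res[[paste0("bias_", g)]] <- distractor_bias_table(dt, group = g)
      }
      res$bias_by_face <- distractor_bias_by_face(dt, group = "in")
      p <- file.path(out_dir, sprintf("drifting_times_%s.csv", cond))
      write.csv(dt, p, row.names = FALSE, quote = FALSE)
      paths[[paste0("dt_", cond)]] <- p
      p <- file.path(out_dir, sprintf("distractor_bias_%s.csv", cond))
      write.csv(rbind(res$bias_in, res$bias_out, res$bias_all), p,
                row.names = FALSE, quote = FALSE)
      paths[[paste0("bias_", cond)]] <- p
    }
    if ("fit" %in% stages) {
      res$fit_sei_in <- grid_search_weights(res$bias_in, matrices, "sei",
                                            step = grid_step)
      res$fit_sei_out <- grid_search_weights(res$bias_out, matrices, "sei",
                                             step = grid_step)
      res$fit_iei_in <- grid_search_weights(res$bias_by_face, matrices, "iei",
                                            step = grid_step)
      for (nm in c("fit_sei_in", "fit_sei_out", "fit_iei_in")) {
        p <- file.path(out_dir, sprintf("%s_%s.json", nm, cond))
        surf <- if (write_surfaces) sub("\\.json$", "_surface.csv", p) else NULL
        write_grid_search(res[[nm]], p, surface_csv = surf)
        paths[[paste0(nm, "_", cond)]] <- p
      }
    }
    per_cond[[cond]] <- res
  }
  results$conditions <- per_cond

  if ("robustness" %in% stages) {
    # run on the baseline condition (first listed)
    base_cond <- conditions[1]
    rb <- withdrawal_robustness(
      distractor_bias_by_face(per_cond[[base_cond]]$dt), alpha = alpha)
    results$robustness <- rb
    paths$robustness <- file.path(out_dir, "withdrawal_robustness.json")
    write_robustness(rb, paths$robustness)
  }

  if ("contrast" %in% stages && all(c("saline", "OT") %in% conditions) &&
      "fit" %in% stages) {
    cc_in <- condition_contrast(per_cond$saline$bias_in, per_cond$OT$bias_in,
                                per_cond$saline$fit_sei_in, per_cond$OT$fit_sei_in)
    cc_out <- condition_contrast(per_cond$saline$bias_out, per_cond$OT$bias_out,
                                 per_cond$saline$fit_sei_out, per_cond$OT$fit_sei_out)
    results$contrast <- list(in_group = cc_in, out_group = cc_out)
    paths$contrast <- file.path(out_dir, "condition_contrast.json")
    jsonlite::write_json(
      lapply(results$contrast, function(cc) {
        out <- unclass(cc)
        out$change_ratios <- as.list(out$change_ratios)
        out$slopes <- as.list(out$slopes)
        out
      }),
      paths$contrast, auto_unbox = TRUE, digits = NA, na = "null")
  }

  # manifest: config, seed, and hashes of every written file
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(lapply(unclass(config), function(v) {
    if (is.null(v)) NULL else as.vector(v)
  }), cfg_path, auto_unbox = TRUE, digits = NA, null = "null")
  paths$config <- cfg_path
  files <- sort(unlist(paths, use.names = FALSE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("socattn")),
    seed = seed, simulated = simulated, stages = stages, alpha = alpha,
    grid_step = grid_step,
    files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(c(results, list(paths = paths, bundle = bundle)))
}
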