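#' Pipeline configuration
#'
#' Bundles the inputs and analysis parameters of [run_pipeline()].
#' Exactly one input source must be given: either a trial table (with an
#' optional trajectory table), or a [sim_config()] to simulate one.
#'
#' @param trials Trial table `data.frame` or CSV path.
#' @param trajectories Optional trajectory table `data.frame` or CSV path.
#' @param simulation Optional [sim_config()]; mutually exclusive with
#'   `trials`.
#' @param kernel_sd Rolling-kernel SD (degrees) for bias curves.
#' @param curve_grid Dissimilarity grid for bias curves.
#' @param surface_time_sd,surface_diss_sd,surface_n_grid,surface_min_trials
#'   Trajectory-surface parameters (ms, degrees, grid points, trials).
#' @param min_per_bin Anisotropy-fit floor per 90-degree bin.
#' @param alpha Pointwise significance level.
#' @param do_trajectory Run the trajectory stage when trajectories exist.
#' @param rt_method `"two_stage"` or `"lmer"` for the RT model.
#' @param output_dir Optional directory for `report.json`, `summary.txt`
#'   and surface CSVs.
#' @param seed Seed for any simulation randomness.
#' @param verbose Log stage progress and trial counts.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(trials = NULL, trajectories = NULL,
                            simulation = NULL, kernel_sd = 20,
                            curve_grid = seq(0, 180, by = 2),
                            surface_time_sd = 120, surface_diss_sd = 20,
                            surface_n_grid = 90, surface_min_trials = 20,
                            min_per_bin = 25, alpha = 0.05,
                            do_trajectory = TRUE,
                            rt_method = c("two_stage", "lmer"),
                            output_dir = NULL, seed = 1L, verbose = TRUE) {
  rt_method <- match.arg(rt_method)
  if (is.null(trials) == is.null(simulation)) {
    stop("exactly one input source required: `trials` or `simulation`")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    stop("`simulation` must be a sim_config()")
  }
  if (!is.null(trials) && !is.null(trajectories) &&
      is.character(trajectories) && !file.exists(trajectories)) {
    stop("trajectory file not found: ", trajectories)
  }
  if (kernel_sd <= 0 || surface_time_sd <= 0 || surface_diss_sd <= 0) {
    stop("kernel parameters must be positive")
  }
  structure(list(trials = trials, trajectories = trajectories,
                 simulation = simulation, kernel_sd = kernel_sd,
                 curve_grid = curve_grid, surface_time_sd = surface_time_sd,
                 surface_diss_sd = surface_diss_sd,
                 surface_n_grid = surface_n_grid,
                 surface_min_trials = surface_min_trials,
                 min_per_bin = min_per_bin, alpha = alpha,
                 do_trajectory = do_trajectory, rt_method = rt_method,
                 output_dir = output_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain any [pipeline_config()] field; a nested
#' `simulation:` mapping is passed to [sim_config()]. Unknown fields are
#' an error.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$simulation)) {
    sim_known <- names(formals(sim_config))
    bad <- setdiff(names(y$simulation), sim_known)
    if (length(bad)) stop("unknown simulation field(s): ", paste(bad, collapse = ", "))
    if (!is.null(y$simulation$bias_amplitude_mean)) {
      y$simulation$bias_amplitude_mean <- unlist(y$simulation$bias_amplitude_mean)
    }
    if (!is.null(y$simulation$conditions)) {
      y$simulation$conditions <- unlist(y$simulation$conditions)
    }
    y$simulation <- do.call(sim_config, y$simulation)
  }
  do.call(pipeline_config, y)
}

#' Run the full serial-bias analysis pipeline
#'
#' Executes simulate/ingest, anisotropy correction, serial-bias
#' estimation (per-subject asymmetries, condition contrast, bias curves),
#' the trajectory stage (bias surfaces, first/last-frame sign analyses)
#' when trajectories are available, Stroop congruency contrasts, and the
#' RT-by-dissimilarity model. Trial counts in/used/excluded are logged
#' and conserved at every stage. With a fixed seed the report is
#' byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return The report, a list of class `"serial_report"`. If
#'   `config$output_dir` is set, `report.json`, `summary.txt` and surface
#'   CSVs are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- input -----------------------------------------------------------
  trajectories <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    log("simulating experiment (seed %d)", config$seed)
    ex <- stage("simulate", simulate_experiment(sim))
    trials <- ex$trials
    trajectories <- ex$trajectories
    ground_truth <- ex$ground_truth
  } else {
    trials <- if (is.character(config$trials)) {
      stage("ingest", read_trials(config$trials))
    } else config$trials
    if (!is.null(config$trajectories)) {
      trajectories <- if (is.character(config$trajectories)) {
        stage("ingest", read_trajectories(config$trajectories))
      } else config$trajectories
    }
    ground_truth <- NULL
  }
  n_in <- nrow(trials)
  counts <- list(input = list(trials_in = n_in, trials_used = n_in,
                              trials_excluded = 0L))
  log("input: %d trials", n_in)

  # --- anisotropy correction ------------------------------------------
  trials <- stage("anisotropy", correct_anisotropy(trials,
                                                   min_per_bin = config$min_per_bin))
  n_out <- sum(trials$is_outlier)
  counts$anisotropy <- list(trials_in = n_in, trials_used = n_in - n_out,
                            trials_excluded = n_out)
  schemes <- tapply(trials$scheme, interaction(trials$participant,
                                               trials$condition, drop = TRUE),
                    function(s) s[1])
  log("anisotropy: %d outliers flagged (%.2f%%); schemes: %d cardinal / %d oblique",
      n_out, 100 * n_out / n_in, sum(schemes == "cardinal"),
      sum(schemes == "oblique"))

  # --- serial bias -----------------------------------------------------
  trials <- stage("serial_prep", serial_prep(trials))
  n_used <- sum(trials$use_serial)
  counts$serial <- list(trials_in = n_in, trials_used = n_used,
                        trials_excluded = n_in - n_used)
  log("serial bias: %d trials usable (%d excluded)", n_used, n_in - n_used)
  est <- stage("serial_bias", per_subject_bias(trials))
  two_conds <- length(unique(est$condition)) == 2
  contrast <- if (two_conds && length(unique(est$participant)) >= 2) {
    stage("serial_bias", condition_bias_contrast(est))
  } else NULL
  curves <- stage("serial_bias",
                  bias_curve_tests(trials, kernel_sd = config$kernel_sd,
                                   grid = config$curve_grid,
                                   alpha = config$alpha))
  group_ci <- NULL
  if (!is.null(contrast)) {
    mat <- as.matrix(contrast$wide[, -1])
    group_ci <- within_subject_ci(mat)
  }

  # --- trajectories ----------------------------------------------------
  traj_res <- NULL
  if (!is.null(trajectories) && config$do_trajectory) {
    log("trajectory stage: %d samples", nrow(trajectories))
    surf <- stage("trajectory",
                  trajectory_bias_surface(trajectories, trials,
                                          time_sd = config$surface_time_sd,
                                          diss_sd = config$surface_diss_sd,
                                          n_grid = config$surface_n_grid,
                                          min_trials = config$surface_min_trials,
                                          alpha = config$alpha))
    fb <- stage("trajectory", frame_bias(trajectories, trials))
    ff <- stage("trajectory", first_frame_sign_analysis(fb))
    fl <- tryCatch(suppressMessages(first_last_sign_model(fb)),
                   error = function(e) list(error = conditionMessage(e)))
    sf <- tryCatch(second_frame_repulsive_fraction(fb),
                   error = function(e) list(error = conditionMessage(e)))
    traj_res <- list(surface = surf, frame_bias = fb, first_frame = ff,
                     first_last = fl, second_frame = sf)
  }

  # --- stroop & RT -----------------------------------------------------
  stroop <- NULL
  if (all(c("stroop_rt", "stroop_color") %in% names(trials))) {
    stroop <- stage("stroop", stroop_congruency_contrast(trials))
  }
  rt_model <- if (two_conds) {
    stage("rt_model", suppressMessages(
      rt_dissimilarity_model(trials, method = config$rt_method)))
  } else NULL

  # --- conservation check ---------------------------------------------
  for (nm in names(counts)) {
    cc <- counts[[nm]]
    stopifnot(cc$trials_in == cc$trials_used + cc$trials_excluded)
  }

  report <- list(
    seed = config$seed,
    parameters = config[c("kernel_sd", "surface_time_sd", "surface_diss_sd",
                          "surface_n_grid", "surface_min_trials",
                          "min_per_bin", "alpha", "rt_method")],
    counts = counts,
    anisotropy = list(outliers_flagged = n_out,
                      schemes = as.list(table(unlist(schemes)))),
    serial_bias = list(
      per_subject = est,
      group_ci = group_ci,
      contrast = if (!is.null(contrast)) contrast$contrast else NULL,
      one_sample = if (!is.null(contrast)) contrast$one_sample else NULL,
      correlation = if (!is.null(contrast)) contrast$correlation else NULL,
      curves = curves),
    trajectory = if (!is.null(traj_res)) list(
      support_ms = traj_res$surface$support_ms,
      clusters = lapply(traj_res$surface$conditions,
                        function(cnd) cnd$cluster_summary),
      first_frame = traj_res$first_frame[c("strata_tests", "condition_contrast")],
      first_last = traj_res$first_last[setdiff(names(traj_res$first_last), "slopes")],
      second_frame = traj_res$second_frame),
    stroop = stroop,
    rt_model = if (!is.null(rt_model)) {
      rt_model[c("estimates", "method", "condition_coding",
                 "n_participants", "n_excluded")]
    } else NULL,
    ground_truth = if (!is.null(ground_truth)) {
      list(latent_sd = ground_truth$latent_sd,
           latent_correlation = ground_truth$latent_correlation)
    } else NULL
  )
  class(report) <- "serial_report"
  attr(report, "surfaces") <- if (!is.null(traj_res)) traj_res$surface else NULL
  attr(report, "trials") <- trials

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$output_dir, "report.json"))
    writeLines(format_report(report), file.path(config$output_dir, "summary.txt"))
    if (!is.null(traj_res)) {
      write_surfaces(traj_res$surface, config$output_dir)
    }
    log("report written to %s", config$output_dir)
  }
  report
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `"serial_report"` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Write trajectory bias surfaces as dense CSV matrices plus metadata
#'
#' @param surfaces A `"bias_surface_set"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_surfaces <- function(surfaces, dir) {
  for (cond in names(surfaces$conditions)) {
    s <- surfaces$conditions[[cond]]
    utils::write.csv(s$bias, file.path(dir, sprintf("surface_bias_%s.csv", cond)),
                     row.names = FALSE)
    utils::write.csv(s$t, file.path(dir, sprintf("surface_t_%s.csv", cond)),
                     row.names = FALSE)
  }
  meta <- list(time_grid_ms = surfaces$time_grid,
               dissimilarity_grid = surfaces$dissimilarity_grid,
               support_ms = surfaces$support_ms, value = surfaces$value,
               params = surfaces$params,
               clusters = lapply(surfaces$conditions, function(cnd) cnd$cluster_summary))
  jsonlite::write_json(meta, file.path(dir, "surface_meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

format_report <- function(report) {
  out <- c("Serial-bias pipeline report", "===========================", "")
  for (nm in names(report$counts)) {
    cc <- report$counts[[nm]]
    out <- c(out, sprintf("%-12s in %6d  used %6d  excluded %5d",
                          nm, cc$trials_in, cc$trials_used, cc$trials_excluded))
  }
  sb <- report$serial_bias
  if (!is.null(sb$contrast)) {
    ct <- sb$contrast
    out <- c(out, "", sprintf(
      "Bias asymmetry: %s %.2f%% [%.2f, %.2f] vs %s %.2f%% [%.2f, %.2f]",
      ct$condition_1, ct$mean_1, ct$lower_1, ct$upper_1,
      ct$condition_2, ct$mean_2, ct$lower_2, ct$upper_2),
      sprintf("  paired t(%d) = %.2f, p = %.4g, d = %.2f",
              ct$df, ct$t, ct$p, ct$d))
  }
  if (!is.null(sb$correlation)) {
    cr <- sb$correlation
    out <- c(out, sprintf("  cross-condition r(%d) = %.2f, p = %.4g",
                          cr$df, cr$estimate, cr$p))
  }
  if (!is.null(report$rt_model)) {
    es <- report$rt_model$estimates
    sl <- es[es$term == "slope_ms_per_deg", ]
    out <- c(out, "", sprintf("RT slope: %.3f ms/deg [%.3f, %.3f] (%s)",
                              sl$estimate, sl$lower, sl$upper,
                              report$rt_model$method))
  }
  if (!is.null(report$trajectory)) {
    out <- c(out, "", sprintf("Trajectory support: up to %.0f ms before response",
                              report$trajectory$support_ms))
    for (cond in names(report$trajectory$clusters)) {
      cs <- report$trajectory$clusters[[cond]]
      out <- c(out, sprintf("  %s: %d significant cluster(s)", cond,
                            if (is.null(nrow(cs))) 0L else nrow(cs)))
    }
  }
  out
}

#' @export
print.serial_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
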