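#' Assemble a full experiment configuration
#'
#' Bundles every stage's parameters for an end-to-end synthetic experiment:
#' trajectory simulation, run schedule, area presets, fitting, decoding, and
#' the population analyses.  The master seed makes the whole pipeline
#' reproducible; per-stage seeds are derived from it with a stable string
#' hash of the stage name, so adding a stage never perturbs the random
#' streams of earlier stages.
#'
#' @param trajectory A [trajectory_config()].
#' @param schedule A [run_schedule()].
#' @param presets An [area_presets()] tibble (any subset of rows).
#' @param fit A [fit_options()].
#' @param grid A [decoding_grid()].
#' @param spec A [stimulus_spec()].
#' @param n_runs Number of runs (default 3; leave-one-run-out CV).
#' @param n_subjects Simulated subjects (default 5).
#' @param methods Decoders to run, subset of `c("ml", "svr")`.
#' @param svr_cost,svr_epsilon SVR hyperparameters.
#' @param exclusion_thresholds Distance-exclusion thresholds, degrees.
#' @param subsample_n,subsample_repeats Matched-voxel-count analysis size
#'   (`NULL` `subsample_n` disables it).
#' @param seed Master seed.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(trajectory = trajectory_config(),
                              schedule = run_schedule(),
                              presets = area_presets(),
                              fit = fit_options(),
                              grid = decoding_grid(),
                              spec = stimulus_spec(),
                              n_runs = 3,
                              n_subjects = 5,
                              methods = "ml",
                              svr_cost = 1,
                              svr_epsilon = 0.1,
                              exclusion_thresholds = seq(0, 4, by = 0.5),
                              subsample_n = NULL,
                              subsample_repeats = 100,
                              seed = 1L) {
  stopifnot(n_runs >= 2, n_subjects >= 1, all(methods %in% c("ml", "svr")))
  structure(
    list(trajectory = trajectory, schedule = schedule, presets = presets,
         fit = fit, grid = grid, spec = spec, n_runs = n_runs,
         n_subjects = n_subjects, methods = methods, svr_cost = svr_cost,
         svr_epsilon = svr_epsilon,
         exclusion_thresholds = exclusion_thresholds,
         subsample_n = subsample_n, subsample_repeats = subsample_repeats,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Derive a per-stage seed from the master seed
#'
#' Stable polynomial hash (base 31 modulo 2^31 - 1) of the stage name,
#' combined with the master seed.
#'
#' @param master Master integer seed.
#' @param stage Stage name, e.g. `"trajectory/subject1"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' Run the full synthetic experiment end-to-end
#'
#' For every simulated subject: simulate a trajectory and volume series; for
#' every preset: sample a ground-truth population, simulate noisy responses,
#' run leave-one-run-out decoding with each configured method, and compute
#' accuracies.  Population analyses (Fisher-z ANOVA across areas, paired
#' horizontal-vs-vertical tests, centre spreads, eccentricity-size curves,
#' distance-exclusion decay fits) are aggregated across subjects.  All
#' artifacts are written as CSV plus a JSON report; identical config and
#' seed give identical bytes.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param run_exclusion Compute the distance-exclusion decay analysis
#'   (moderately expensive; default TRUE).
#' @return The report, invisibly a list with elements `accuracy` (tibble:
#'   subject, area, method, r_horizontal, r_vertical), `fits_summary`,
#'   `spreads`, `ecc_size`, `group_stats`, `decay` (when run), `config_seed`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           run_exclusion = TRUE) {
  t0 <- Sys.time()
  msg <- function(...) message(sprintf(...))
  sched <- config$schedule
  fr <- config$trajectory$frame_rate
  n_frames <- config$n_runs * frames_per_run(sched, fr)

  accuracy <- list()
  fits_summary <- list()
  spreads <- list()
  ecc_rows <- list()
  decay_rows <- list()
  decoded_all <- list()

  for (subj in seq_len(config$n_subjects)) {
    tcfg <- config$trajectory
    tcfg$seed <- stage_seed(config$seed, paste0("trajectory/subject", subj))
    traj <- simulate_trajectory(tcfg, n_frames)
    volumes <- frames_to_volumes(traj, sched, config$n_runs, fr)
    msg("[prfdecode] subject %d: %d volumes in %d runs", subj,
        nrow(volumes), config$n_runs)

    for (pi in seq_len(nrow(config$presets))) {
      preset <- config$presets[pi, ]
      pop_seed <- stage_seed(config$seed,
                             sprintf("population/subject%d/%s", subj,
                                     preset$area))
      pop <- sample_population(preset, seed = pop_seed,
                               span_half_width = config$fit$span_half_width)
      series <- simulate_responses(
        pop, volumes, config$spec,
        seed = stage_seed(config$seed,
                          sprintf("responses/subject%d/%s", subj,
                                  preset$area))
      )

      for (method in config$methods) {
        dec <- cross_validate(series, volumes, method = method,
                              fit_opts = config$fit, grid = config$grid,
                              spec = config$spec, cost = config$svr_cost,
                              epsilon = config$svr_epsilon)
        acc <- prediction_accuracy(dec)
        accuracy[[length(accuracy) + 1]] <- dplyr::mutate(
          acc, subject = subj, area = preset$area, method = toupper(method),
          n_selected_min = min(attr(dec, "n_selected")),
          .before = 1
        )
        decoded_all[[length(decoded_all) + 1]] <-
          dplyr::mutate(dec, subject = subj, area = preset$area)
      }

      # full-data fits for RF-property summaries (size, spread, eccentricity)
      fits <- fit_prf_population(series, volumes, config$fit, config$spec)
      sel <- suppressWarnings(select_voxels(fits, config$fit))
      fits_summary[[length(fits_summary) + 1]] <- tibble::tibble(
        subject = subj, area = preset$area, n_voxels = nrow(fits),
        n_selected = nrow(sel),
        mean_sigma = if (nrow(sel)) mean(sel$sigma) else NA_real_,
        mean_fit_r = mean(fits$fit_r)
      )
      if (nrow(sel) >= 2) {
        spreads[[length(spreads) + 1]] <- dplyr::mutate(
          center_spread(sel), subject = subj, area = preset$area, .before = 1
        )
        ecc_rows[[length(ecc_rows) + 1]] <- dplyr::mutate(
          eccentricity_size_curve(sel), subject = subj, area = preset$area,
          .before = 1
        )
      }
      if (run_exclusion && nrow(sel) >= 2) {
        curve <- distance_exclusion_curve(
          sel, series, volumes, thresholds = config$exclusion_thresholds,
          grid = config$grid, spec = config$spec
        )
        dfit <- fit_exponential_decay(curve)
        decay_rows[[length(decay_rows) + 1]] <- tibble::tibble(
          subject = subj, area = preset$area, tau = dfit$tau,
          amplitude = dfit$amplitude, baseline = dfit$baseline,
          identifiable = dfit$identifiable
        )
      }
      msg("[prfdecode] subject %d preset %s done (%.1f s elapsed)", subj,
          preset$area, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }
  }

  accuracy <- dplyr::bind_rows(accuracy)
  fits_summary <- dplyr::bind_rows(fits_summary)
  spreads <- dplyr::bind_rows(spreads)
  ecc_size <- dplyr::bind_rows(ecc_rows)
  decay <- dplyr::bind_rows(decay_rows)

  group_stats <- experiment_group_stats(accuracy, fits_summary)

  report <- list(
    accuracy = accuracy, fits_summary = fits_summary, spreads = spreads,
    ecc_size = ecc_size, group_stats = group_stats, decay = decay,
    config_seed = config$seed
  )
  if (!is.null(out_dir)) {
    write_report(report, decoded_all, out_dir)
  }
  invisible(report)
}

# Fisher-z ANOVA across areas (per axis), and paired horizontal-vs-vertical
# t tests per area, when the design is large enough.
experiment_group_stats <- function(accuracy, fits_summary) {
  out <- list()
  for (method in unique(accuracy$method)) {
    am <- dplyr::filter(accuracy, .data$method == !!method)
    n_areas <- dplyr::n_distinct(am$area)
    n_subj <- dplyr::n_distinct(am$subject)
    if (n_areas >= 2 && n_subj >= 2) {
      for (axis in c("r_horizontal", "r_vertical")) {
        z <- fisher_z(pmin(pmax(am[[axis]], -0.999999), 0.999999))
        g <- split(z, am$area)
        st <- one_way_f(g)
        out[[length(out) + 1]] <- dplyr::mutate(
          st, method = method, test = paste0("anova_areas_", axis),
          .before = 1
        )
      }
    }
    if (n_subj >= 2) {
      for (area in unique(am$area)) {
        aa <- dplyr::filter(am, .data$area == !!area)
        zt <- fisher_z(pmin(pmax(aa$r_horizontal, -0.999999), 0.999999))
        zv <- fisher_z(pmin(pmax(aa$r_vertical, -0.999999), 0.999999))
        st <- paired_t(zt, zv)
        out[[length(out) + 1]] <- dplyr::mutate(
          st, method = method,
          test = paste0("paired_h_vs_v_", area), .before = 1
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

write_report <- function(report, decoded_all, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
  }
  wr(report$accuracy, "accuracy")
  wr(report$fits_summary, "fits_summary")
  if (nrow(report$spreads)) wr(report$spreads, "center_spreads")
  if (nrow(report$ecc_size)) wr(report$ecc_size, "eccentricity_size")
  if (nrow(report$group_stats)) wr(report$group_stats, "group_stats")
  if (!is.null(report$decay) && nrow(report$decay)) wr(report$decay, "decay")
  if (length(decoded_all)) {
    wr(dplyr::bind_rows(decoded_all), "decoded")
  }
  jsonlite::write_json(
    lapply(report, function(x) if (inherits(x, "data.frame")) x else x),
    file.path(out_dir, "report.json"),
    dataframe = "rows", digits = 10, pretty = TRUE
  )
  invisible(NULL)
}

#' Generate a ready-made synthetic fixture configuration
#'
#' `"tiny"` is a single V1-like preset of 20 voxels with two single-block
#' runs and one subject: the full pipeline decodes in seconds, for tests and
#' examples.  `"small"` is shaped like the full study: six presets, 200
#' voxels per area, three full runs, five subjects.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Master seed.
#' @param noise_sd Override the presets' noise SD (`NULL` keeps defaults).
#' @return An [experiment_config()].
#' @export
make_fixture_config <- function(size = c("tiny", "small"), seed = 1,
                                noise_sd = NULL) {
  size <- match.arg(size)
  if (size == "tiny") {
    presets <- area_presets(n_voxels = 20)[1, ]
    cfg <- experiment_config(
      schedule = run_schedule(n_blocks = 1),
      presets = presets, n_runs = 2, n_subjects = 1,
      exclusion_thresholds = seq(0, 3, by = 0.5), seed = seed
    )
  } else {
    cfg <- experiment_config(seed = seed)
  }
  if (!is.null(noise_sd)) cfg$presets$noise_sd <- noise_sd
  cfg
}

#' Write a fixture bundle to a directory
#'
#' Simulates the fixture experiment (trajectory, volumes, ground-truth
#' population, responses) without fitting or decoding, and writes each table
#' as CSV so any downstream stage can be exercised from serialized inputs.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Invisibly, the list of written file paths.
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 1, out_dir) {
  cfg <- make_fixture_config(size, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tcfg <- cfg$trajectory
  tcfg$seed <- stage_seed(cfg$seed, "trajectory/subject1")
  n_frames <- cfg$n_runs * frames_per_run(cfg$schedule, tcfg$frame_rate)
  traj <- simulate_trajectory(tcfg, n_frames)
  volumes <- frames_to_volumes(traj, cfg$schedule, cfg$n_runs,
                               tcfg$frame_rate)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(x, p)
    p
  }
  paths <- c(paths, wr(traj, "trajectory"), wr(volumes, "volumes"))
  for (pi in seq_len(nrow(cfg$presets))) {
    preset <- cfg$presets[pi, ]
    pop <- sample_population(
      preset,
      seed = stage_seed(cfg$seed, sprintf("population/subject1/%s",
                                          preset$area)),
      span_half_width = cfg$fit$span_half_width
    )
    series <- simulate_responses(
      pop, volumes, cfg$spec,
      seed = stage_seed(cfg$seed, sprintf("responses/subject1/%s",
                                          preset$area))
    )
    paths <- c(paths,
               wr(pop, paste0("population_", preset$area)),
               wr(series, paste0("responses_", preset$area)))
  }
  invisible(paths)
}

#' Read an experiment configuration from JSON
#'
#' @param path Path to a JSON file with (optional) sections `trajectory`,
#'   `schedule`, `fit`, `decoding`, `experiment`; missing fields fall back
#'   to defaults.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  take <- function(ctor, section) {
    args <- js[[section]]
    if (is.null(args)) ctor() else do.call(ctor, as.list(args))
  }
  cfg <- experiment_config(
    trajectory = take(trajectory_config, "trajectory"),
    schedule = take(run_schedule, "schedule"),
    fit = take(fit_options, "fit"),
    spec = take(stimulus_spec, "stimulus")
  )
  ex <- js$experiment
  for (f in intersect(names(ex),
                      c("n_runs", "n_subjects", "methods", "svr_cost",
                        "svr_epsilon", "exclusion_thresholds",
                        "subsample_n", "subsample_repeats", "seed"))) {
    cfg[[f]] <- ex[[f]]
  }
  if (!is.null(js$presets)) {
    if (is.character(js$presets)) {
      cfg$presets <- dplyr::filter(area_presets(),
                                   .data$area %in% js$presets)
    } else {
      cfg$presets <- tibble::as_tibble(js$presets)
    }
  }
  cfg
}
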