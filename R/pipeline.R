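# Pipeline orchestration: JSON config, staged commands
# (simulate / estimate / features / analyze / classify), run manifests, and
# the command-line entry point used by `inst/cli/gaitpath`.

#' Default pipeline configuration
#'
#' Every stage setting with its default; the full (defaulted) config is
#' serialized into each run manifest so runs are self-describing.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    fs = 100,
    sensor = list(sampling_rate = 100, accel_range = 8, gyro_range = 1000),
    cohort = list(
      counts = list(mild_pd = 2L, advanced_pd = 2L, healthy_older = 2L,
                    healthy_young = 2L),
      strides_per_session = 72L
    ),
    noise = list(
      accel_noise_sd = 0.08, gyro_noise_sd = 0.02,
      accel_bias = c(0.02, -0.015, 0.01), gyro_bias = c(0.002, -0.001, 0.0015),
      hs_spike_amplitude = 10, hs_spike_width = 0.06
    ),
    estimation = list(
      segmentation = "midstance", band = c(8, 25), k_mad = 4,
      min_stride_time = 0.6, toe_off_method = "gyro",
      support_change_convention = "contralateral_toe_off_after_terminal_hs",
      quota = 20L
    ),
    stats = list(alpha = 0.05, pa_reps = 1000L, pa_percentile = 95),
    classifier = list(kernel = "rbf", box_constraint = 1,
                      kernel_scale = "auto", standardize = TRUE)
  )
}

#' Load and validate a pipeline config (JSON), filling defaults
#' @param path JSON file, or `NULL` for pure defaults.
#' @return validated config list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
    # participant counts replace the defaults wholesale (a mapping, not
    # per-field settings to merge)
    if (!is.null(user$cohort$counts)) cfg$cohort$counts <- user$cohort$counts
  }
  problems <- validate_pipeline_config(cfg)
  if (length(problems)) {
    stop("invalid config: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  cfg
}

validate_pipeline_config <- function(cfg) {
  p <- character(0)
  chk_num <- function(x, nm, pos = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || (pos && x <= 0)) {
      p <<- c(p, sprintf("`%s` must be a positive number", nm))
    }
  }
  chk_num(cfg$seed, "seed", pos = FALSE)
  chk_num(cfg$fs, "fs")
  chk_num(cfg$sensor$sampling_rate, "sensor.sampling_rate")
  if (!is.list(cfg$cohort$counts) && !is.numeric(cfg$cohort$counts)) {
    p <- c(p, "`cohort.counts` must be a named mapping")
  }
  if (!is.null(cfg$estimation$segmentation) &&
      !cfg$estimation$segmentation %in% c("midstance", "heelstrike")) {
    p <- c(p, "`estimation.segmentation` must be 'midstance' or 'heelstrike'")
  }
  if (!is.null(cfg$classifier$kernel) &&
      !cfg$classifier$kernel %in% c("rbf", "linear", "polynomial")) {
    p <- c(p, "`classifier.kernel` unknown")
  }
  alpha <- cfg$stats$alpha
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    p <- c(p, "`stats.alpha` must be in (0,1)")
  }
  p
}

config_to_objects <- function(cfg) {
  counts <- unlist(cfg$cohort$counts)
  list(
    cohort = cohort_spec(
      counts = counts,
      strides_per_session = cfg$cohort$strides_per_session,
      turn_indices = cfg$cohort$turn_indices,
      seed = cfg$seed
    ),
    noise = sensor_noise(
      accel_noise_sd = cfg$noise$accel_noise_sd,
      gyro_noise_sd = cfg$noise$gyro_noise_sd,
      accel_bias = cfg$noise$accel_bias,
      gyro_bias = cfg$noise$gyro_bias,
      hs_spike_amplitude = cfg$noise$hs_spike_amplitude,
      hs_spike_width = cfg$noise$hs_spike_width
    ),
    estimation = do.call(estimation_config, cfg$estimation)
  )
}

write_manifest <- function(out_dir, stage, cfg, outputs, warnings = character(0)) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("gaitpath")),
    config = cfg,
    outputs = lapply(outputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    warnings = warnings
  )
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate stage: write session CSVs, truth sidecars, truth feature table
#' @param cfg config list (see [load_pipeline_config()]).
#' @param out_dir output directory (created).
#' @export
cmd_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_to_objects(cfg)
  cohort <- simulate_cohort(make_default_profiles(), obj$cohort, obj$noise,
                            quota = cfg$estimation$quota, fs = cfg$fs)
  outputs <- character(0)
  for (pid in names(cohort$sessions)) {
    sim <- cohort$sessions[[pid]]
    for (side in c("left", "right")) {
      f <- file.path(out_dir, sprintf("%s_%s.csv", pid, side))
      write_imu_csv(sim$session[[side]], f)
      outputs <- c(outputs, f)
    }
    tf <- file.path(out_dir, sprintf("%s.truth.json", pid))
    jsonlite::write_json(
      list(participant_id = pid, group = sim$session$group,
           strides = sim$truth$strides),
      tf, auto_unbox = TRUE, digits = NA
    )
    outputs <- c(outputs, tf)
  }
  ff <- file.path(out_dir, "truth_features.csv")
  utils::write.csv(cohort$truth_features, ff, row.names = FALSE)
  outputs <- c(outputs, ff)
  write_manifest(out_dir, "simulate", cfg, outputs)
  invisible(cohort)
}

read_session_dir <- function(dir, cfg) {
  lefts <- sort(list.files(dir, pattern = "_left\\.csv$", full.names = TRUE))
  spec <- sensor_spec(cfg$sensor$sampling_rate, cfg$sensor$accel_range,
                      cfg$sensor$gyro_range)
  lapply(lefts, function(lf) {
    pid <- sub("_left\\.csv$", "", basename(lf))
    rf <- file.path(dir, paste0(pid, "_right.csv"))
    if (!file.exists(rf)) stop("missing right-leg file for ", pid, call. = FALSE)
    group <- NA_character_
    tj <- file.path(dir, paste0(pid, ".truth.json"))
    if (file.exists(tj)) group <- jsonlite::fromJSON(tj)$group
    walk_session(pid, group,
                 read_imu_csv(lf, spec, "left"),
                 read_imu_csv(rf, spec, "right"), spec)
  })
}

#' Estimate stage: per-stride trajectories and drop log
#' @param cfg config list.
#' @param sessions_dir directory of session CSVs (from [cmd_simulate()]).
#' @param out_dir output directory.
#' @export
cmd_estimate <- function(cfg, sessions_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- read_session_dir(sessions_dir, cfg)
  if (!length(sessions)) stop("no sessions found in ", sessions_dir, call. = FALSE)
  est_cfg <- do.call(estimation_config, cfg$estimation)
  outputs <- character(0)
  drops <- list()
  for (s in sessions) {
    est <- estimate_trajectories(s, est_cfg)
    long <- list()
    for (side in c("left", "right")) {
      for (j in seq_along(est[[side]])) {
        tr <- est[[side]][[j]]$trajectory
        long[[length(long) + 1L]] <- data.frame(
          side = side, stride = j, time_s = tr$time,
          forward_m = tr$position[, "forward"],
          lateral_m = tr$position[, "lateral"],
          vertical_m = tr$position[, "vertical"]
        )
      }
    }
    f <- file.path(out_dir, sprintf("%s_trajectories.csv", s$participant_id))
    utils::write.csv(do.call(rbind, long), f, row.names = FALSE)
    outputs <- c(outputs, f)
    if (nrow(est$dropped)) {
      drops[[s$participant_id]] <- est$dropped
    }
  }
  dl <- file.path(out_dir, "dropped_strides.json")
  jsonlite::write_json(drops, dl, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, dl)
  write_manifest(out_dir, "estimate", cfg, outputs)
  invisible(outputs)
}

#' Feature stage: participant feature table CSV
#' @param cfg config list.
#' @param sessions_dir directory of session CSVs.
#' @param out_dir output directory.
#' @export
cmd_features <- function(cfg, sessions_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- read_session_dir(sessions_dir, cfg)
  if (!length(sessions)) stop("no sessions found in ", sessions_dir, call. = FALSE)
  est_cfg <- do.call(estimation_config, cfg$estimation)
  warn <- character(0)
  withCallingHandlers(
    table <- cohort_features(sessions, est_cfg),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  f <- file.path(out_dir, "feature_table.csv")
  utils::write.csv(table, f, row.names = FALSE)
  write_manifest(out_dir, "features", cfg, f, warnings = warn)
  invisible(table)
}

#' Analyze stage: ANOVA + Shaffer + PCA + parallel analysis reports
#' @param cfg config list.
#' @param features_csv feature table CSV path.
#' @param out_dir output directory.
#' @export
cmd_analyze <- function(cfg, features_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  if (!all(c("group", "F1", "V3") %in% names(table))) {
    stop("malformed feature table: ", features_csv, call. = FALSE)
  }
  res <- analyze_features(table, alpha = cfg$stats$alpha,
                          reps = cfg$stats$pa_reps,
                          percentile = cfg$stats$pa_percentile,
                          seed = cfg$seed)
  jf <- file.path(out_dir, "analysis.json")
  jsonlite::write_json(
    list(
      per_variable = lapply(res$per_variable, function(v) {
        list(anova = v$anova, posthoc = v$posthoc)
      }),
      pca = res$pca[c("sdev", "variance_proportion", "cumulative_proportion",
                      "loadings")],
      parallel_analysis = res$parallel[c("n_components", "observed",
                                         "thresholds", "reps", "percentile",
                                         "seed")]
    ),
    jf, auto_unbox = TRUE, digits = NA
  )
  tf <- file.path(out_dir, "pca_table.txt")
  writeLines(format_pca_table(res$pca), tf)
  write_manifest(out_dir, "analyze", cfg, c(jf, tf))
  invisible(res)
}

format_pca_table <- function(pca) {
  k <- length(pca$sdev)
  c(
    paste(c("Principal component    ", sprintf("%8d", seq_len(k))), collapse = ""),
    paste(c("Standard deviation     ", sprintf("%8.3f", pca$sdev)), collapse = ""),
    paste(c("Variance proportion    ", sprintf("%8.3f", pca$variance_proportion)),
          collapse = ""),
    paste(c("Cumulative proportion  ", sprintf("%8.3f", pca$cumulative_proportion)),
          collapse = "")
  )
}

#' Classify stage: pair-suite accuracies, confusion matrices, ROC points
#' @param cfg config list.
#' @param features_csv feature table CSV path.
#' @param out_dir output directory.
#' @export
cmd_classify <- function(cfg, features_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  if (length(unique(table$group)) < 2L) {
    stop("need at least two groups to classify", call. = FALSE)
  }
  spec <- classifier_spec(
    kernel = cfg$classifier$kernel,
    box_constraint = cfg$classifier$box_constraint,
    kernel_scale = cfg$classifier$kernel_scale,
    standardize = cfg$classifier$standardize,
    seed = cfg$seed
  )
  suite <- run_pair_suite(table, spec = spec)
  outputs <- character(0)
  af <- file.path(out_dir, "accuracy.csv")
  utils::write.csv(as.data.frame(suite$accuracy), af)
  outputs <- c(outputs, af)
  roc_rows <- list()
  for (pname in names(suite$results)) {
    cv <- suite$results[[pname]]$pc2
    cf <- file.path(out_dir, sprintf(
      "confusion_%s.csv", gsub("[^a-z_]+", "_", pname)
    ))
    utils::write.csv(as.data.frame.matrix(cv$confusion), cf)
    outputs <- c(outputs, cf)
    roc <- roc_curve(cv$scores, cv$labels)
    roc_rows[[pname]] <- data.frame(
      pair = pname, fpr = roc$fpr, tpr = roc$tpr, auc = roc$auc
    )
  }
  rf <- file.path(out_dir, "roc_points.csv")
  utils::write.csv(do.call(rbind, roc_rows), rf, row.names = FALSE)
  outputs <- c(outputs, rf)
  write_manifest(out_dir, "classify", cfg, outputs)
  invisible(suite)
}

#' Command-line entry point
#'
#' `gaitpath simulate|estimate|features|analyze|classify|run-all
#'  --config <json> --out <dir>`. Exit codes: 0 ok, 2 usage/config error,
#' 3 data error.
#'
#' @param args character vector (e.g. `commandArgs(TRUE)`).
#' @return integer exit status (invisibly); the CLI wrapper passes it to
#'   `quit()`.
#' @export
gaitpath_main <- function(args = commandArgs(TRUE)) {
  usage <- paste(
    "usage: gaitpath <simulate|estimate|features|analyze|classify|run-all>",
    "--config <json> --out <dir> [--sessions <dir>] [--features <csv>]"
  )
  if (!length(args)) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, out = "gaitpath_out", sessions = NULL,
              features = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message("bad argument: ", args[i], "\n", usage)
      return(invisible(2L))
    }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- tryCatch(load_pipeline_config(opt$config), error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(invisible(2L))
  }
  sessions_dir <- opt$sessions %||% file.path(opt$out, "sessions")
  features_csv <- opt$features %||% file.path(opt$out, "features", "feature_table.csv")
  run <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message("error: ", conditionMessage(e))
      3L
    })
  }
  status <- switch(cmd,
    simulate = run(cmd_simulate(cfg, file.path(opt$out, "sessions"))),
    estimate = run(cmd_estimate(cfg, sessions_dir, file.path(opt$out, "trajectories"))),
    features = run(cmd_features(cfg, sessions_dir, file.path(opt$out, "features"))),
    analyze = run(cmd_analyze(cfg, features_csv, file.path(opt$out, "analysis"))),
    classify = run(cmd_classify(cfg, features_csv, file.path(opt$out, "classification"))),
    `run-all` = run({
      cmd_simulate(cfg, file.path(opt$out, "sessions"))
      cmd_estimate(cfg, file.path(opt$out, "sessions"), file.path(opt$out, "trajectories"))
      cmd_features(cfg, file.path(opt$out, "sessions"), file.path(opt$out, "features"))
      fcsv <- file.path(opt$out, "features", "feature_table.csv")
      cmd_analyze(cfg, fcsv, file.path(opt$out, "analysis"))
      cmd_classify(cfg, fcsv, file.path(opt$out, "classification"))
    }),
    {
      message("unknown command: ", cmd, "\n", usage)
      2L
    }
  )
  invisible(status)
}
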