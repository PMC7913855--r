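# End-to-end orchestration: preprocess -> extract -> cluster ->
# classify -> enumerate -> fit/score/select -> evaluate, with every
# stage artifact written to a run directory plus a reproducibility
# manifest.

#' Assemble and validate a pipeline run configuration
#'
#' @param training Path to the training recordings file, or a recordings
#'   tibble.
#' @param evaluation Optional held-out recordings (path or tibble). When
#'   absent, evaluation runs on the training recordings (native frames).
#' @param column_map Column map for [read_recordings()] (path or list).
#' @param out_dir Directory stage artifacts are written into.
#' @param sample_rate,cutoff,filter_order,vel_threshold,min_run,n_frames
#'   Preprocessing parameters (see [preprocess_recordings()]).
#' @param var_threshold Cumulative-variance retention threshold, in (0, 1].
#' @param fixed_k Optional fixed synergy count per subject.
#' @param min_subject_fraction,cc_high,cc_low,cc_candidate Cluster
#'   classification thresholds (see [classify_clusters()]).
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed matters when the inputs are simulated).
#' @return A validated `run_config` list.
#' @export
run_config <- function(training, evaluation = NULL, column_map = NULL,
                       out_dir = tempfile("handsyn-run-"),
                       sample_rate = 100, cutoff = 5, filter_order = 2,
                       vel_threshold = 2, min_run = 0.2, n_frames = 1000,
                       var_threshold = 0.95, fixed_k = NULL,
                       min_subject_fraction = 0.10, cc_high = 0.8,
                       cc_low = 0.3, cc_candidate = 0.4, seed = 1L) {
  cfg <- list(
    training = training, evaluation = evaluation, column_map = column_map,
    out_dir = out_dir, sample_rate = sample_rate, cutoff = cutoff,
    filter_order = filter_order, vel_threshold = vel_threshold,
    min_run = min_run, n_frames = n_frames, var_threshold = var_threshold,
    fixed_k = fixed_k, min_subject_fraction = min_subject_fraction,
    cc_high = cc_high, cc_low = cc_low, cc_candidate = cc_candidate,
    seed = as.integer(seed)
  )
  if (cfg$var_threshold <= 0 || cfg$var_threshold > 1) {
    abort("`var_threshold` must lie in (0, 1].")
  }
  for (nm in c("min_subject_fraction", "cc_high", "cc_low", "cc_candidate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  if (cfg$cutoff <= 0 || cfg$sample_rate <= 2 * cfg$cutoff) {
    abort("need `sample_rate` > 2 * `cutoff` > 0.")
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map one-to-one onto [run_config()] arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

#' Run the full sensor-reduction pipeline
#'
#' Executes every stage in order, writing each stage's artifact as CSV
#' into `config$out_dir` together with a JSON manifest (config hash,
#' package version, per-stage timings). Any stage error halts the run
#' with the stage name; artifacts of completed stages are retained.
#'
#' @param config A `run_config` (or a path read via [read_run_config()]).
#' @return Invisibly, a list with every stage result (`preprocessed`,
#'   `synergies`, `partition`, `classification`, `combinations`,
#'   `scores`, `bank`, `rom`, `report`) plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "handsyn",
    version = as.character(utils::packageVersion("handsyn")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = list()
  )
  res <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      completed = TRUE,
      seconds = round(proc.time()[["elapsed"]] - t0, 3)
    )
    out
  }
  load_recs <- function(x) {
    if (is.character(x)) read_recordings(x, config$column_map)
    else check_recordings(x)
  }

  raw <- t_stage("read", load_recs(config$training))
  res$preprocessed <- t_stage("preprocess", {
    out <- preprocess_recordings(
      raw, cutoff = config$cutoff, order = config$filter_order,
      sample_rate = config$sample_rate, vel_threshold = config$vel_threshold,
      min_run = config$min_run, n_frames = config$n_frames
    )
    write_recordings(out, file.path(config$out_dir, "preprocessed.csv"))
    out
  })
  res$synergies <- t_stage("extract", {
    syn <- extract_synergies(res$preprocessed,
                             var_threshold = config$var_threshold,
                             fixed_k = config$fixed_k)
    readr::write_csv(tidy(syn), file.path(config$out_dir, "synergies.csv"))
    readr::write_csv(glance(syn),
                     file.path(config$out_dir, "synergies_summary.csv"))
    syn
  })
  res$partition <- t_stage("cluster", {
    part <- cluster_synergies(res$synergies)
    readr::write_csv(part$assignment,
                     file.path(config$out_dir, "cluster_assignment.csv"))
    readr::write_csv(tidy(part),
                     file.path(config$out_dir, "cluster_summary.csv"))
    readr::write_csv(linkage_table(part$tree),
                     file.path(config$out_dir, "linkage.csv"))
    part
  })
  res$classification <- t_stage("classify", {
    cls <- classify_clusters(
      res$partition, min_subject_fraction = config$min_subject_fraction,
      cc_high = config$cc_high, cc_low = config$cc_low,
      cc_candidate = config$cc_candidate
    )
    readr::write_csv(classification_table(cls),
                     file.path(config$out_dir, "classification.csv"))
    cls
  })
  res$combinations <- t_stage("enumerate", {
    combos <- enumerate_combinations(res$classification)
    flat <- combos |>
      dplyr::mutate(representative = vapply(.data$representative,
                                            paste, "", collapse = ";"))
    readr::write_csv(flat, file.path(config$out_dir, "combinations.csv"))
    combos
  })
  res$scores <- t_stage("fit_select", {
    sc <- score_and_select(res$preprocessed, res$combinations)
    readr::write_csv(glance(sc), file.path(config$out_dir, "scores.csv"))
    readr::write_csv(tidy(sc$best_bank),
                     file.path(config$out_dir, "coefficients.csv"))
    sc
  })
  res$bank <- res$scores$best_bank
  eval_out <- t_stage("evaluate", {
    eval_raw <- if (is.null(config$evaluation)) raw
                else load_recs(config$evaluation)
    eval_data <- preprocess_recordings(
      eval_raw, cutoff = config$cutoff, order = config$filter_order,
      sample_rate = config$sample_rate, vel_threshold = config$vel_threshold,
      min_run = config$min_run, resample = FALSE
    )
    rom <- rom_table(res$preprocessed, eval_data)
    rep <- evaluate_estimators(res$bank, eval_data, rom)
    readr::write_csv(rom, file.path(config$out_dir, "rom.csv"))
    readr::write_csv(rep$global, file.path(config$out_dir, "global_errors.csv"))
    readr::write_csv(rep$per_activity,
                     file.path(config$out_dir, "activity_errors.csv"))
    readr::write_csv(rep$activity_avg,
                     file.path(config$out_dir, "activity_avg.csv"))
    list(rom = rom, report = rep)
  })
  res$rom <- eval_out$rom
  res$report <- eval_out$report
  manifest$representative <- res$bank$representative
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

config_hash <- function(config) {
  plain <- config
  plain$training <- if (is.character(plain$training)) plain$training else "<tibble>"
  plain$evaluation <- if (is.character(plain$evaluation %||% "")) plain$evaluation else "<tibble>"
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(plain, tf, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tf))
}

# Flat merge list of an hclust tree: one row per merge with the two
# children (negative = leaf index) and the merge height in degrees.
linkage_table <- function(tree) {
  tibble::tibble(
    merge = seq_len(nrow(tree$merge)),
    left = tree$merge[, 1],
    right = tree$merge[, 2],
    height = tree$height
  )
}

classification_table <- function(cls) {
  cls$table |>
    dplyr::mutate(candidates = vapply(.data$candidates, paste, "",
                                      collapse = ";"))
}

#' Reproduce the full study from local copies of the deposited datasets
#'
#' Runs the complete pipeline on the two public whole-hand kinematics
#' archives this methodology was developed on (training: 22 subjects x
#' 26 activities; evaluation: 20 subjects x 33 activities, right hand),
#' provided as delimited text exports in the package's input layout.
#' The archives are not shipped with the package; download them and
#' point `data_dir` at a directory containing `training.csv` and
#' `evaluation.csv` (plus optional `column_map.yml`).
#'
#' @param data_dir Directory holding the dataset exports.
#' @param out_dir Run directory (default: under `tempdir()`).
#' @return The [run_pipeline()] result list.
#' @export
reproduce_study <- function(data_dir, out_dir = tempfile("handsyn-study-")) {
  training <- file.path(data_dir, "training.csv")
  evaluation <- file.path(data_dir, "evaluation.csv")
  if (!file.exists(training) || !file.exists(evaluation)) {
    abort(sprintf(
      paste0("deposited datasets not found under '%s': expected ",
             "training.csv and evaluation.csv"), data_dir
    ), class = "handsyn_missing_data")
  }
  cmap <- file.path(data_dir, "column_map.yml")
  run_pipeline(run_config(
    training = training, evaluation = evaluation,
    column_map = if (file.exists(cmap)) cmap else NULL,
    out_dir = out_dir
  ))
}
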