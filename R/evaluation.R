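# Held-out evaluation: apply a fitted estimator bank to a new cohort at
# native frame rate and report errors in degrees and as a percentage of
# each joint's range of motion (RoM).

#' Per-DoF range of motion over one or more datasets
#'
#' RoM of a joint is the pooled maximum minus pooled minimum angle over
#' every frame of every supplied dataset (training and evaluation
#' together, so the denominator reflects the full excursion ever
#' observed for that joint).
#'
#' @param ... Recordings tibbles (at least one).
#' @return Tibble `dof`, `rom` (degrees).
#' @export
rom_table <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  mats <- lapply(sets, function(d) angles_matrix(check_recordings(d)))
  all <- do.call(rbind, mats)
  rom <- apply(all, 2, max) - apply(all, 2, min)
  if (any(rom <= 0)) {
    abort(sprintf("degenerate RoM (zero range) for: %s",
                  paste(dof_labels()[rom <= 0], collapse = ", ")),
          class = "handsyn_degenerate_rom")
  }
  tibble::tibble(dof = dof_labels(), rom = unname(rom))
}

#' Evaluate an estimator bank on a recording collection
#'
#' Estimates every non-representative DoF on every frame of `data`
#' (native frame counts — no time normalization, so long activities
#' weigh in proportion to their true duration) and reports:
#'
#' * global per-DoF RMSE across all frames and subjects (one value per
#'   joint), in degrees and as %RoM;
#' * per-activity per-DoF RMSE (across subjects and frames of each
#'   activity), in degrees and as %RoM, plus each activity's mean %RoM
#'   across DoF (the "AVG" column).
#'
#' @param bank An `estimator_bank`.
#' @param data Recordings tibble (filtered and trimmed; not resampled).
#' @param rom RoM tibble from [rom_table()] (pass both training and
#'   evaluation data there when available).
#' @return An `error_report` object: list with `global` (tibble `dof`,
#'   `rmse`, `pct_rom`), `per_activity` (tibble `task`, `dof`,
#'   `n_frames`, `rmse`, `pct_rom`), `activity_avg` (tibble `task`,
#'   `avg_pct_rom`), `rom`, `representative`.
#' @export
evaluate_estimators <- function(bank, data, rom) {
  stopifnot(inherits(bank, "estimator_bank"))
  data <- check_recordings(data)
  counts <- dplyr::count(data, .data$task)
  empty <- counts$task[counts$n == 0]
  if (length(empty) > 0) {
    warn(sprintf("skipping activity with zero frames: %s",
                 paste(empty, collapse = ", ")))
  }
  rec <- angles_matrix(data)[, bank$estimated, drop = FALSE]
  est <- cbind(1, angles_matrix(data)[, bank$representative, drop = FALSE]) %*%
    coef_matrix(bank)
  rom_est <- rom$rom[match(bank$estimated, rom$dof)]
  if (anyNA(rom_est)) abort("`rom` must cover every estimated DoF.")

  sq <- (est - rec)^2
  grmse <- unname(sqrt(colMeans(sq)))
  global <- tibble::tibble(
    dof = bank$estimated,
    rmse = grmse,
    pct_rom = 100 * grmse / rom_est
  )

  per_activity <- tibble::as_tibble(as.data.frame(sq)) |>
    dplyr::mutate(task = data$task) |>
    tidyr::pivot_longer(-"task", names_to = "dof", values_to = "sq") |>
    dplyr::group_by(.data$task, .data$dof) |>
    dplyr::summarise(n_frames = dplyr::n(), rmse = sqrt(mean(.data$sq)),
                     .groups = "drop") |>
    dplyr::mutate(
      pct_rom = 100 * .data$rmse / rom_est[match(.data$dof, bank$estimated)],
      dof = factor(.data$dof, levels = dof_labels())
    ) |>
    dplyr::arrange(.data$task, .data$dof) |>
    dplyr::mutate(dof = as.character(.data$dof))

  activity_avg <- per_activity |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(avg_pct_rom = mean(.data$pct_rom), .groups = "drop")

  structure(
    list(global = global, per_activity = per_activity,
         activity_avg = activity_avg, rom = rom,
         representative = bank$representative),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> %d estimated DoF, %d activities; global RMSE %.2f-%.2f deg (%.1f-%.1f%% RoM)\n",
    nrow(x$global), nrow(x$activity_avg),
    min(x$global$rmse), max(x$global$rmse),
    min(x$global$pct_rom), max(x$global$pct_rom)
  ))
  invisible(x)
}

#' @describeIn evaluate_estimators Per-activity x DoF error table.
#' @param x An `error_report`.
#' @param ... Unused.
#' @method tidy error_report
#' @export
tidy.error_report <- function(x, ...) x$per_activity

#' @describeIn evaluate_estimators One-row summary: mean/max global RMSE
#'   and %RoM, activity-average %RoM range.
#' @method glance error_report
#' @export
glance.error_report <- function(x, ...) {
  tibble::tibble(
    mean_rmse = mean(x$global$rmse),
    max_rmse = max(x$global$rmse),
    mean_pct_rom = mean(x$global$pct_rom),
    max_pct_rom = max(x$global$pct_rom),
    min_activity_avg = min(x$activity_avg$avg_pct_rom),
    max_activity_avg = max(x$activity_avg$avg_pct_rom)
  )
}

#' Export recorded-versus-estimated traces
#'
#' Long-format table of one recording's estimated DoF for
#' estimated-vs-recorded trace plots.
#'
#' @param bank An `estimator_bank`.
#' @param data Recordings tibble (typically one subject x task).
#' @return Tibble `subject`, `task`, `frame`, `dof`, `recorded`,
#'   `estimated` with `frames x n_estimated` rows per recording.
#' @export
export_traces <- function(bank, data) {
  data <- check_recordings(data)
  est <- estimate_angles(bank, data)
  rec_long <- data |>
    dplyr::select(dplyr::all_of(.id_cols), dplyr::all_of(bank$estimated)) |>
    tidyr::pivot_longer(dplyr::all_of(bank$estimated),
                        names_to = "dof", values_to = "recorded")
  est_long <- est |>
    tidyr::pivot_longer(dplyr::all_of(bank$estimated),
                        names_to = "dof", values_to = "estimated")
  dplyr::left_join(rec_long, est_long,
                   by = c("subject", "task", "frame", "dof"))
}
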