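#' Read joint-angle recordings from delimited text
#'
#' Reads a CSV/TSV file holding one or more whole-hand recordings and
#' returns them as a single tidy tibble with one row per frame. The file
#' must have a header naming a subject column, a task column and the 16
#' DoF columns; frames are taken in file order within each
#' (subject, task) block. Angles are expected in degrees relative to the
#' flat-hand reference posture (hand resting flat, fingers together),
#' which is zero for every joint.
#'
#' Files whose headers differ from the canonical [dof_labels()] can be
#' mapped with a column-map configuration, so external datasets can be
#' ingested without code changes.
#'
#' @param path Path to a delimited text file (delimiter inferred from the
#'   extension: `.tsv`/`.tab` read as TAB, anything else as comma).
#' @param column_map Either `NULL` (file headers already canonical, with
#'   `subject` and `task` columns), a path to a YAML or JSON file, or a
#'   list, with elements `subject`, `task` (names of the id columns in the
#'   file) and `dof` (named list mapping each canonical DoF label to the
#'   file column holding it). Omitted `dof` entries default to the
#'   canonical label itself.
#' @return A tibble with columns `subject`, `task`, `frame` and the 16 DoF
#'   columns in canonical order.
#' @seealso [write_recordings()], [dof_labels()]
#' @export
read_recordings <- function(path, column_map = NULL) {
  cmap <- resolve_column_map(column_map)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )

  needed <- c(cmap$subject, cmap$task, unlist(cmap$dof))
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "File '%s' is missing required column(s): %s.",
      path, paste(missing, collapse = ", ")
    ), class = "handsyn_format_error")
  }

  ang_cols <- unlist(cmap$dof)
  for (cn in ang_cols) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      abort(sprintf(
        "Non-numeric angle value in column '%s' of '%s' (data row %d).",
        cn, path, if (is.na(bad)) 1L else bad
      ), class = "handsyn_parse_error")
    }
  }

  out <- tibble::tibble(
    subject = as.character(raw[[cmap$subject]]),
    task = as.character(raw[[cmap$task]])
  )
  for (lab in dof_labels()) out[[lab]] <- as.numeric(raw[[cmap$dof[[lab]]]])
  out <- out |>
    dplyr::group_by(.data$subject, .data$task) |>
    dplyr::mutate(frame = dplyr::row_number()) |>
    dplyr::ungroup()
  check_recordings(out)
}

#' Write joint-angle recordings to delimited text
#'
#' Writes a recordings tibble in the same layout [read_recordings()]
#' consumes (canonical headers), so processed recordings round-trip.
#'
#' @param data Recordings tibble (`subject`, `task`, `frame`, 16 DoF columns).
#' @param path Output file path; `.tsv` writes TAB-delimited, else CSV.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(data, path) {
  data <- check_recordings(data)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

resolve_column_map <- function(column_map) {
  if (is.character(column_map) && length(column_map) == 1) {
    column_map <- if (grepl("\\.json$", column_map, ignore.case = TRUE)) {
      jsonlite::read_json(column_map, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(column_map)
    }
  }
  if (is.null(column_map)) column_map <- list()
  if (!is.list(column_map)) abort("`column_map` must be NULL, a path or a list.")
  cmap <- list(
    subject = column_map$subject %||% "subject",
    task = column_map$task %||% "task",
    dof = as.list(setNames(dof_labels(), dof_labels()))
  )
  for (lab in names(column_map$dof %||% list())) {
    if (!lab %in% dof_labels()) {
      abort(sprintf("Unknown DoF label '%s' in column map.", lab))
    }
    cmap$dof[[lab]] <- column_map$dof[[lab]]
  }
  cmap
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-DoF normalization parameters
#'
#' Serializes the per-DoF mean and standard deviation produced by
#' [zscore_concat()] as a small CSV (`dof,mean,sd`).
#'
#' @param params Tibble with columns `dof`, `mean`, `sd`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_normalization <- function(params, path) {
  stopifnot(all(c("dof", "mean", "sd") %in% names(params)))
  readr::write_csv(params, path)
  invisible(path)
}
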