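# Canonical vocabulary of the 16 recorded hand degrees of freedom.
# Ordering is fixed: every matrix and every wide tibble the package
# produces uses exactly this column order.

.dof_table <- tibble::tribble(
  ~dof,       ~digit, ~kind,
  "CMC1F",     1L,    "flexion",
  "CMC1A",     1L,    "abduction",
  "MCP1F",     1L,    "flexion",
  "IP1F",      1L,    "flexion",
  "MCP2F",     2L,    "flexion",
  "PIP2F",     2L,    "flexion",
  "MCP3F",     3L,    "flexion",
  "PIP3F",     3L,    "flexion",
  "MCP4F",     4L,    "flexion",
  "PIP4F",     4L,    "flexion",
  "MCP5F",     5L,    "flexion",
  "PIP5F",     5L,    "flexion",
  "MCP2-3A",   2L,    "abduction",
  "MCP3-4A",   3L,    "abduction",
  "MCP4-5A",   4L,    "abduction",
  "PalmArch",  5L,    "arch"
)

#' Canonical hand degree-of-freedom labels
#'
#' The package records and estimates the 16 anatomical hand angles measured
#' by a whole-hand instrumented glove: flexion of the metacarpophalangeal
#' (MCP) joints of thumb and fingers, thumb interphalangeal (IP) and finger
#' proximal interphalangeal (PIP) flexions, thumb carpometacarpal (CMC)
#' flexion and abduction, the three relative finger abductions, and the
#' palmar arch. Digits are numbered 1 (thumb) to 5 (little finger);
#' `F` = flexion/extension, `A` = abduction/adduction.
#'
#' @return `dof_labels()` returns a character vector of the 16 labels in
#'   canonical order. `dof_info()` returns a tibble with columns `dof`,
#'   `digit` and `kind` (`"flexion"`, `"abduction"` or `"arch"`).
#' @examples
#' dof_labels()
#' dof_info()
#' @export
dof_labels <- function() .dof_table$dof

#' @rdname dof_labels
#' @export
dof_info <- function() .dof_table

# Columns every recordings tibble must carry besides the angles.
.id_cols <- c("subject", "task", "frame")

# Validate a recordings tibble: subject/task/frame plus the 16 DoF columns,
# all angle values finite. Returns the data with DoF columns in canonical
# order (invisibly reordered).
check_recordings <- function(data, arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame of recordings.", arg))
  }
  missing_id <- setdiff(.id_cols, names(data))
  if (length(missing_id) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing_id, collapse = ", ")
    ))
  }
  missing_dof <- setdiff(dof_labels(), names(data))
  if (length(missing_dof) > 0) {
    abort(sprintf(
      "`%s` is missing DoF column(s): %s.",
      arg, paste(missing_dof, collapse = ", ")
    ), class = "handsyn_format_error")
  }
  ang <- as.matrix(data[dof_labels()])
  if (!is.numeric(ang) || !all(is.finite(ang))) {
    abort(sprintf("`%s` contains non-finite or non-numeric angle values.", arg),
          class = "handsyn_format_error")
  }
  dplyr::select(data, dplyr::all_of(.id_cols), dplyr::all_of(dof_labels()))
}

# Extract the frames x 16 angle matrix of one (subject, task) block,
# in canonical column order.
angles_matrix <- function(data) {
  m <- as.matrix(data[dof_labels()])
  rownames(m) <- NULL
  m
}

# Apply a per-recording matrix transform f(matrix, ...) -> matrix to each
# (subject, task) block of a recordings tibble, reassembling a tibble with
# fresh frame indices.
map_recordings <- function(data, f, ...) {
  data <- check_recordings(data)
  data |>
    dplyr::group_by(.data$subject, .data$task) |>
    dplyr::group_modify(function(d, key) {
      m <- f(as.matrix(d[dof_labels()]), ...)
      out <- tibble::as_tibble(as.data.frame(m))
      names(out) <- dof_labels()
      out$frame <- seq_len(nrow(out))
      dplyr::relocate(out, "frame")
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(.id_cols), dplyr::all_of(dof_labels()))
}
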