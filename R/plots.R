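# ggplot2 displays for the main result objects. These are deliberately
# plain: loading heatmaps, a dendrogram, score profiles and error maps,
# each returning a ggplot the caller can restyle.

#' @describeIn extract_synergies Heatmap of rotated loadings, one facet
#'   per subject.
#' @param object A `hand_synergies` object.
#' @method autoplot hand_synergies
#' @export
autoplot.hand_synergies <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(dof = factor(.data$dof, levels = rev(dof_labels())))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$component), y = .data$dof, fill = .data$loading
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(~subject) +
    ggplot2::labs(x = "rotated component", y = NULL, fill = "CC") +
    ggplot2::theme_minimal()
}

#' @describeIn select_partition Dendrogram of the complete-linkage tree
#'   with the selected cut marked.
#' @param object A `synergy_partition`.
#' @method autoplot synergy_partition
#' @export
autoplot.synergy_partition <- function(object, ...) {
  tree <- object$tree
  # segment coordinates from the merge list
  n <- length(tree$order)
  leaf_x <- setNames(seq_len(n), tree$order)
  pos <- matrix(NA_real_, nrow(tree$merge), 2) # x, height of each merge
  segs <- list()
  node_x <- function(id) {
    if (id < 0) leaf_x[[as.character(-id)]] else pos[id, 1]
  }
  node_h <- function(id) if (id < 0) 0 else pos[id, 2]
  for (i in seq_len(nrow(tree$merge))) {
    l <- tree$merge[i, 1]; r <- tree$merge[i, 2]
    xl <- node_x(l); xr <- node_x(r); h <- tree$height[i]
    pos[i, ] <- c((xl + xr) / 2, h)
    segs[[length(segs) + 1]] <- data.frame(
      x = c(xl, xl, xr), xend = c(xl, xr, xr),
      y = c(node_h(l), h, h), yend = c(h, h, node_h(r))
    )
  }
  segdf <- do.call(rbind, segs)
  ggplot2::ggplot(segdf) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::geom_hline(yintercept = object$cut_distance,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "pooled synergies", y = "angle between components (deg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn score_and_select Mean training RMSE per combination, best
#'   highlighted.
#' @param object A `combination_scores`.
#' @method autoplot combination_scores
#' @export
autoplot.combination_scores <- function(object, ...) {
  df <- dplyr::mutate(object$scores, best = .data$set_id == object$best_id)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$set_id), y = .data$mean_rmse, fill = .data$best
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "combination", y = "mean RMSE across estimated DoF (deg)") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_estimators Heatmap of per-activity %RoM errors
#'   with the across-DoF average as an extra column.
#' @param object An `error_report`.
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object, ...) {
  df <- object$per_activity |>
    dplyr::select("task", "dof", "pct_rom") |>
    dplyr::bind_rows(
      dplyr::mutate(object$activity_avg, dof = "AVG",
                    pct_rom = .data$avg_pct_rom) |>
        dplyr::select("task", "dof", "pct_rom")
    ) |>
    dplyr::mutate(dof = factor(.data$dof, levels = c(dof_labels(), "AVG")))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$dof, y = .data$task, fill = .data$pct_rom
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "% RoM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot recorded versus estimated traces
#'
#' @param traces Long tibble from [export_traces()].
#' @return A ggplot: one facet per estimated DoF, recorded and estimated
#'   traces overlaid.
#' @export
plot_traces <- function(traces) {
  df <- tidyr::pivot_longer(traces, c("recorded", "estimated"),
                            names_to = "series", values_to = "angle")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$frame, y = .data$angle, colour = .data$series
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~dof, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}
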