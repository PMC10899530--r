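# QC plotting helpers.

#' Plot single-cell activity traces
#'
#' Spaghetti plot of per-cell ERK activity over time with treatment and
#' MEKi addition marked; the ensemble mean is overlaid.
#'
#' @param traces Trace tibble.
#' @param schedule Optional [acquisition_schedule()] used to mark event
#'   times.
#' @param max_cells Cap on the number of cells drawn (sampled
#'   deterministically by cell id).
#' @return A ggplot.
#' @export
plot_traces <- function(traces, schedule = NULL, max_cells = 50) {
  require_columns(traces, c("cell_id", "time_min", "activity"), "`traces`")
  ids <- sort(unique(traces$cell_id))
  if (length(ids) > max_cells) ids <- ids[seq_len(max_cells)]
  d <- traces[traces$cell_id %in% ids & is.finite(traces$activity), ]
  m <- dplyr::summarise(dplyr::group_by(d, .data$time_min),
                        activity = mean(.data$activity), .groups = "drop")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min / 60,
                                       y = .data$activity,
                                       group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_line(data = m, ggplot2::aes(group = NULL),
                       color = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "ERK activity (KTR ratio)") +
    ggplot2::theme_minimal()
  if (!is.null(schedule)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(schedule$treatment_time, schedule$meki_time) / 60,
      linetype = "dashed", color = "grey40")
  }
  p
}

#' Plot a segmented tissue section
#'
#' Shows the lung mask with tumor components outlined, a quick visual QC
#' of [segment_tissue()] / [segment_tumor()] output.
#'
#' @param tissue_mask Logical lung mask.
#' @param tumor_labels Integer tumor label matrix.
#' @return A ggplot.
#' @export
plot_section <- function(tissue_mask, tumor_labels) {
  df <- tibble::tibble(
    row = as.vector(row(tissue_mask)),
    col = as.vector(col(tissue_mask)),
    what = dplyr::case_when(
      as.vector(tumor_labels) > 0 ~ "tumor",
      as.vector(tissue_mask) ~ "lung",
      TRUE ~ "background"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$what)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(background = "grey95",
                                          lung = "steelblue",
                                          tumor = "firebrick")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
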