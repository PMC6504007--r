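# ggplot2 helpers for the pipeline's result tables.

#' Plot successive-stage DEG counts
#'
#' Bar chart of up/down-regulated gene counts per stage transition, faceted
#' by group.
#'
#' @param transitions Tibble from [successive_stage_degs()].
#' @return A ggplot object.
#' @export
plot_transitions <- function(transitions) {
  df <- transitions |>
    mutate(transition = paste(.data$stage_from, "→", .data$stage_to)) |>
    mutate(transition = factor(.data$transition,
                               levels = unique(.data$transition))) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    mutate(direction = ifelse(.data$direction == "n_up", "up", "down"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$transition, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "stage transition", y = "DEGs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot gene-panel trajectories
#'
#' Mean FPKM per stage, one panel per gene, coloured by group; replicate
#' values shown as points.
#'
#' @param trajectories Tibble from [panel_trajectories()].
#' @param ordering Stage ordering for the x axis.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, ordering = DEFAULT_STAGES) {
  df <- trajectories |>
    mutate(stage = factor(.data$stage,
                          levels = ordering[ordering %in% .data$stage]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$mean_fpkm,
                                   colour = .data$group,
                                   group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(y = .data$fpkm), alpha = 0.5,
                        size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_name), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "FPKM", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot PCA sample coordinates
#'
#' @param object An `embryo_pca`.
#' @param sample_sheet Optional sample sheet for colouring by stage/group.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot embryo_pca
#' @export
autoplot.embryo_pca <- function(object, sample_sheet = NULL, ...) {
  df <- object$scores
  if (!is.null(sample_sheet)) {
    df <- dplyr::left_join(df, sample_sheet, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(sample_sheet)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage,
                                         shape = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise R-squared heatmap
#'
#' @param r2 Matrix from [pairwise_r2()].
#' @return A ggplot object.
#' @export
plot_r2 <- function(r2) {
  df <- as_tibble(r2, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "r2") |>
    mutate(sample_a = factor(.data$sample_a, levels = rownames(r2)),
           sample_b = factor(.data$sample_b, levels = colnames(r2)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
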