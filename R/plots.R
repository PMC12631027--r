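#' Plot PC1-PC2 scores with class-mean confidence ellipses
#'
#' @param object An `eag_pca` from [fit_wave_pca()].
#' @param labels Class label per fitted wave.
#' @param level Confidence level of the mean ellipses.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eag_pca
#' @export
autoplot.eag_pca <- function(object, labels, level = 0.95, ...) {
  sc <- tibble::tibble(PC1 = object$scores[, 1], PC2 = object$scores[, 2],
                       class = as.character(labels))
  ell <- class_ellipses(object$scores, labels, level = level)
  theta <- seq(0, 2 * pi, length.out = 181)
  ell_pts <- purrr::pmap_dfr(ell, function(label, center_x, center_y,
                                           semi_major, semi_minor,
                                           orientation_rad, level, n) {
    x0 <- semi_major * cos(theta); y0 <- semi_minor * sin(theta)
    tibble::tibble(
      class = label,
      PC1 = center_x + x0 * cos(orientation_rad) - y0 * sin(orientation_rad),
      PC2 = center_y + x0 * sin(orientation_rad) + y0 * cos(orientation_rad))
  })
  evr <- object$explained_variance_ratio
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_polygon(data = ell_pts,
                          ggplot2::aes(fill = .data$class), alpha = 0.25,
                          colour = NA) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * evr[2]),
                  colour = "odor", fill = "odor") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-split balanced accuracies
#'
#' The dashed line marks the accuracy expected from random guessing
#' (1 / number of classes).
#'
#' @param object An `eag_eval` from [evaluate_repeated()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eag_eval
#' @export
autoplot.eag_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_split,
                  ggplot2::aes(.data$model, .data$balanced_accuracy,
                               fill = .data$model)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$chance_level,
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "balanced accuracy") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pooled row-normalized confusion matrix
#'
#' @param eval An `eag_eval`.
#' @param model Which model's matrix to draw (`"svm"` or `"rf"`).
#' @return A ggplot.
#' @export
plot_confusion <- function(eval, model = "svm") {
  M <- eval$confusion_percent[[model]]
  df <- tibble::as_tibble(as.data.frame(as.table(M)))
  names(df) <- c("truth", "predicted", "percent")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", .data$percent))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = toupper(model), fill = "%") +
    ggplot2::theme_minimal()
}

#' Plot mean waveforms per odor
#'
#' @param waves Wave tibble.
#' @param by Grouping column (default `"odor"`).
#' @return A ggplot of per-group mean voltage traces.
#' @export
plot_mean_waves <- function(waves, by = "odor") {
  info <- wave_table_info(waves)
  t_axis <- (seq_len(info$n_samples) - 1) / info$sample_rate_hz - info$pre_s
  df <- waves |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(mean_wave = list(Reduce(`+`, .data$samples) / dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(t = list(t_axis)) |>
    tidyr::unnest(c("mean_wave", "t"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$mean_wave,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "voltage (norm.)",
                  colour = by) +
    ggplot2::theme_minimal()
}
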