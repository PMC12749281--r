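#' Accuracy-vs-information quadrant scatter
#'
#' Scatter of the entropy-removal fraction (y) against Youden's J (x)
#' for every feature, with dashed cutlines at the quadrant thresholds
#' and the four quadrant labels annotated. The plot is deterministic
#' (no jitter): identical inputs give identical output.
#'
#' @param results Results data frame from [compute_feature_table()] or
#'   [read_results()].
#' @param j_cut,er_cut Cutline positions (defaults 0.60 and 0.40).
#' @param file Optional output path; written as PNG or SVG according to
#'   the file extension.
#' @param width,height Device size in inches when `file` is given.
#' @return The ggplot object, invisibly when `file` is given.
#' @examples
#' ft <- generate_cohort(synth_config(n_features = 50, seed = 1))
#' p <- quadrant_plot(compute_feature_table(ft))
#' @export
quadrant_plot <- function(results, j_cut = 0.60, er_cut = 0.40,
                          file = NULL, width = 7, height = 5) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    validation_error("'results' must be a non-empty data frame")
  }
  missing_cols <- setdiff(c("youden_j", "er_fraction"), names(results))
  if (length(missing_cols)) {
    schema_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }

  df <- results
  df$quadrant <- classify_quadrant(df$youden_j, df$er_fraction, j_cut, er_cut)
  labels <- data.frame(
    x = c(1, 1, -1, -1), y = c(1, 0, 1, 0),
    hjust = c(1, 1, 0, 0), vjust = c(1, 0, 1, 0),
    lab = c("High Accuracy\nHigh Information", "High Accuracy\nLow Information",
            "Low Accuracy\nHigh Information", "Low Accuracy\nLow Information")
  )

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$youden_j, y = .data$er_fraction)) +
    ggplot2::geom_vline(xintercept = j_cut, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = er_cut, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$quadrant), alpha = 0.75, size = 1.8) +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$lab,
                   hjust = .data$hjust, vjust = .data$vjust),
      inherit.aes = FALSE, size = 3, colour = "grey30"
    ) +
    ggplot2::scale_x_continuous(limits = c(-1, 1)) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "Youden's J (accuracy)",
      y = "Entropy removed (% of parent entropy)",
      colour = "Quadrant",
      title = "Diagnostic accuracy vs information gain"
    ) +
    ggplot2::theme_minimal()

  if (is.null(file)) return(p)

  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    grDevices::png(file, width = width, height = height, units = "in", res = 150)
  } else if (ext == "svg") {
    grDevices::svg(file, width = width, height = height)
  } else {
    validation_error(sprintf("unsupported plot format '.%s' (use .png or .svg)", ext))
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(p)
}
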