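# ggplot2 displays of the pipeline's result types.

#' Plot surviving candidate counts along the cascade
#'
#' @param report Filter-report tibble from [run_cascade()].
#' @return A ggplot object.
#' @export
plot_filter_report <- function(report) {
  df <- mutate(as_tibble(report),
    stage = factor(.data$stage, levels = .data$stage)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$surviving)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$surviving), vjust = -0.4) +
    ggplot2::labs(
      x = NULL, y = "surviving RDD candidates",
      title = "Candidates after each filter stage"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' @export
autoplot.rdd_filter_report <- function(object, ...) {
  plot_filter_report(object)
}

#' Plot a base-change spectrum
#'
#' @param spectrum Spectrum tibble from [change_spectrum()].
#' @return A ggplot object.
#' @export
plot_change_spectrum <- function(spectrum) {
  ggplot2::ggplot(
    spectrum,
    ggplot2::aes(
      stats::reorder(.data$collapsed_label, -.data$proportion),
      .data$proportion,
      fill = .data$is_canonical
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "grey60"),
      name = "canonical"
    ) +
    ggplot2::labs(
      x = "base change (strand-collapsed)", y = "proportion of candidates"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rdd_change_spectrum <- function(object, ...) {
  plot_change_spectrum(object)
}

#' Plot editing levels across tissues and stages
#'
#' @param measurements Tibble from [generate_editing_level_dataset()] (or
#'   any table with `tissue`, `stage`, `editing_level`).
#' @return A ggplot object.
#' @export
plot_editing_levels <- function(measurements) {
  ggplot2::ggplot(
    measurements,
    ggplot2::aes(.data$stage, .data$editing_level, colour = .data$tissue)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "developmental stage", y = "editing level") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
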