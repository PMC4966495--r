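# ggplot2 autoplot methods for the package's data and result types.

#' Plot a chromatogram
#'
#' @param object A `chromatogram`.
#' @param peaks Optional [detect_peaks()] result to annotate apices and
#'   boundaries.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromatogram <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (min)", y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p +
      ggplot2::geom_vline(data = as_tibble(peaks),
                          ggplot2::aes(xintercept = .data$apex_time),
                          linetype = "dotted", colour = "grey50") +
      ggplot2::geom_text(data = as_tibble(peaks),
                         ggplot2::aes(x = .data$apex_time,
                                      y = .data$height,
                                      label = .data$label),
                         vjust = -0.5, size = 3)
  }
  p
}

#' Plot a continuum mass spectrum
#'
#' @param object A `mass_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mass_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "m/z (Th)", y = "Intensity") +
    ggplot2::theme_minimal()
}

#' Plot deconvolved neutral masses
#'
#' @param object A `deconvolved_masses` result.
#' @param ... Unused.
#' @return A ggplot object (stick plot of score vs neutral mass).
#' @export
autoplot.deconvolved_masses <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$neutral_mass, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$neutral_mass, yend = 0)) +
    ggplot2::labs(x = "Neutral average mass (Da)", y = "Comb score") +
    ggplot2::theme_minimal()
}

#' Plot a DAR report as a drug-load distribution
#'
#' @param object A `dar_report` or `dar_replicate_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of relative area by drug load.
#' @export
autoplot.dar_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(as.data.frame(object)),
                  ggplot2::aes(x = factor(.data$load), y = .data$area_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Drug load", y = "Relative area (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dar_report
#' @export
autoplot.dar_replicate_report <- autoplot.dar_report
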