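#' Plot a parameter sweep
#'
#' Precision-recall scatter of every sweep row, colored by F1, with the best
#' row (by [select_best()]) highlighted.
#'
#' @param object A `chim_sweep` tibble from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chim_sweep
#' @export
autoplot.chim_sweep <- function(object, ...) {
  best <- select_best(object, attr(object, "base_params") %||% detector_params())
  ggplot2::ggplot(object, ggplot2::aes(x = recall, y = precision, color = f1)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = best, shape = 1, size = 4, color = "black") +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", color = "F1",
                  title = "Chimera detection parameter sweep") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the detector's evidence-score distribution
#'
#' Histogram of the chimera evidence score h by verdict; useful for judging
#' how far the call population sits from the `minh` threshold.
#'
#' @param calls A calls tibble from [detect_chimeras()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_h_distribution <- function(calls, bins = 40) {
  dat <- calls |> filter(.data$has_model)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$h, fill = verdict)) +
    ggplot2::geom_histogram(bins = bins, position = "stack") +
    ggplot2::labs(x = "evidence score h", y = "queries",
                  title = "Chimera evidence scores") +
    ggplot2::theme_minimal()
}

#' Plot false-negative read structure
#'
#' Read-length distribution stratified by 5.8S multiplicity, the signature
#' separating library-prep concatemers (two or more 5.8S copies, long) from
#' ordinary reads.
#'
#' @param report Output of [fn_structure_report()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_fn_structure <- function(report, bins = 30) {
  dat <- report$per_read |>
    mutate(group = ifelse(n_58s >= 2, ">= 2 copies of 5.8S", "0-1 copies"))
  ggplot2::ggplot(dat, ggplot2::aes(x = length_bp, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8, position = "identity") +
    ggplot2::labs(x = "read length (bp)", y = "reads", fill = NULL,
                  title = "False-negative chimera structure") +
    ggplot2::theme_minimal()
}
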