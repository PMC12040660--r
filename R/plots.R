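#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Mean spectrum with standard-deviation ribbon per group
#'
#' The usual cohort overview figure: per-class mean intensity across
#' spectra, with a one-standard-deviation ribbon.
#'
#' @param ds spectra tibble (raw or preprocessed).
#' @return a ggplot.
#' @export
plot_mean_spectra <- function(ds) {
  validate_spectra(ds)
  long <- ds |>
    tidyr::pivot_longer(-dplyr::all_of(.meta_cols),
                        names_to = "wavenumber", values_to = "intensity") |>
    dplyr::mutate(wavenumber = as.numeric(.data$wavenumber)) |>
    dplyr::group_by(.data$group, .data$wavenumber) |>
    dplyr::summarise(mean = mean(.data$intensity), sd = stats::sd(.data$intensity),
                     .groups = "drop")
  ggplot(long, aes(.data$wavenumber, .data$mean,
                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(aes(ymin = .data$mean - .data$sd,
                             ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (a.u.)", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a VIP profile
#' @param object a `vip_profile` tibble.
#' @param threshold reference cutoff drawn as a dashed line (default 1).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vip_profile <- function(object, threshold = 1, ...) {
  ggplot(object, aes(.data$wavenumber, .data$vip)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "VIP") +
    ggplot2::theme_minimal()
}

#' Plot per-iteration metric distributions of a protocol run
#' @param object a `sers_protocol`.
#' @param ... unused.
#' @return a ggplot (boxplots of the four metrics, train vs test).
#' @exportS3Method ggplot2::autoplot
autoplot.sers_protocol <- function(object, ...) {
  long <- object$per_iteration |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "accuracy", "auc"),
                        names_to = "metric")
  ggplot(long, aes(.data$metric, .data$value, fill = .data$subsample)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Metric value", fill = NULL) +
    ggplot2::theme_minimal()
}
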