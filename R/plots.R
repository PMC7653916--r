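#' Plot signed-deviation summaries
#'
#' Mean +/- SD of the signed deviations per variable, split into position
#' and orientation panels — the graphical counterpart of the accuracy
#' tables.
#'
#' @param x An `mdm_validation` object ([run_validation()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdm_validation <- function(x, ...) {
  tabs <- x$tables
  df <- dplyr::bind_rows(
    dplyr::mutate(tabs$position, panel = "position (mm)"),
    dplyr::mutate(tabs$orientation, panel = "orientation (deg)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~panel, scales = "free", ncol = 1) +
    ggplot2::labs(x = NULL, y = "signed deviation (T2' - T2)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ICP convergence
#'
#' Trimmed RMS residual across accepted iterations; the curve is monotone
#' non-increasing by construction.
#'
#' @param x An `icp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icp_result <- function(x, ...) {
  df <- tibble::tibble(iteration = seq_along(x$history), rms = x$history)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$rms)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "accepted iteration", y = "trimmed RMS (mm)") +
    ggplot2::theme_bw()
}

#' Plot reliability coefficients
#'
#' Intra- and inter-examiner ICC per coordinate variable for each
#' superimposition method.
#'
#' @param reliability The `reliability$icc` tibble of an `mdm_validation`,
#'   or the object itself.
#' @return A ggplot object.
#' @export
plot_reliability <- function(reliability) {
  if (inherits(reliability, "mdm_validation")) {
    reliability <- reliability$reliability$icc
  }
  if (is.null(reliability)) stop("no reliability results to plot",
                                 call. = FALSE)
  df <- tidyr::pivot_longer(reliability, cols = c("icc_intra", "icc_inter"),
                            names_to = "kind", values_to = "icc")
  df$kind <- sub("^icc_", "", df$kind)
  ggplot2::ggplot(df, ggplot2::aes(.data$variable, .data$icc,
                                   shape = .data$kind)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~method, ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(min(0.8, min(df$icc, na.rm = TRUE)),
                                      1)) +
    ggplot2::labs(x = NULL, y = "ICC", shape = "examiner") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
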