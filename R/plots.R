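# ggplot2 presentation helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a voltage trace
#'
#' Membrane potential against time with the pulse window shaded.
#'
#' @param object A \code{ca1_trace}.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ca1_trace <- function(object, ...) {
  p <- attr(object, "protocol")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$V)) +
    ggplot2::annotate("rect", xmin = p$pulse_onset,
                      xmax = p$pulse_onset + p$pulse_duration,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Plot conditional-GAN training diagnostics
#'
#' Generator/discriminator losses per iteration and the checkpoint JSD with
#' the selected iteration marked.
#'
#' @param object A \code{ganpop_cgan}.
#' @param ... Unused.
#' @return A ggplot (faceted).
#' @export
autoplot.ganpop_cgan <- function(object, ...) {
  losses <- object$log |>
    tidyr::pivot_longer(c("d_loss", "g_loss"), names_to = "curve")
  jsd_tbl <- dplyr::mutate(object$jsd_log, curve = "jsd")
  dat <- dplyr::bind_rows(
    losses[, c("iteration", "curve", "value")],
    dplyr::rename(jsd_tbl, value = "jsd")[, c("iteration", "curve", "value")]
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_iteration,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~curve, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Feature distributions by group
#'
#' Kernel-density plots of each feature, optionally split by a grouping
#' column.
#'
#' @param features Feature tibble (13 canonical columns), optionally with a
#'   grouping column.
#' @param by Name of the grouping column (NULL for none).
#' @return A ggplot faceted by feature.
#' @export
plot_feature_distributions <- function(features, by = NULL) {
  value_cols <- intersect(feature_names(), names(features))
  long <- tidyr::pivot_longer(features, dplyr::all_of(value_cols),
                              names_to = "feature")
  aes <- if (is.null(by)) {
    ggplot2::aes(x = .data$value)
  } else {
    ggplot2::aes(x = .data$value, colour = .data[[by]])
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}
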