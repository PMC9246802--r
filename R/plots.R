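#' Plot a concentration-time profile
#'
#' Log-scale unbound concentration versus time, one line per compartment,
#' optionally with a horizontal IC50 reference.
#'
#' @param object A `cns_profile`.
#' @param compartments Compartments to draw (default: brain ECF/ICF, CSF
#'   SAS and plasma if present).
#' @param ic50 Optional unbound IC50 (ng/mL) drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cns_profile
#' @export
autoplot.cns_profile <- function(object,
                                 compartments = NULL,
                                 ic50 = NULL, ...) {
  compartments <- compartments %||%
    intersect(c("plasma", "brain_ECF", "brain_ICF", "CSF_SAS"),
              unique(object$compartment))
  df <- object[object$compartment %in% compartments & object$conc > 0, ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 60,
                                         y = .data$conc,
                                         colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "unbound concentration (ng/mL)",
                  colour = NULL,
                  title = paste(attr(object, "drug"),
                                attr(object, "population"))) +
    ggplot2::theme_minimal()
  if (!is.null(ic50)) {
    gg <- gg + ggplot2::geom_hline(yintercept = ic50, linetype = "dashed")
  }
  gg
}

#' Tornado-style plot of a one-at-a-time sensitivity analysis
#'
#' @param x A `cns_sensitivity` tibble from [oat_sensitivity()].
#' @param metric Which percent-change column to draw (default `cmax_pct`).
#' @param compartment Compartment to show (default `"brain_ECF"`).
#' @param top_n Keep the `top_n` most influential parameters.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(x, metric = "cmax_pct",
                             compartment = "brain_ECF", top_n = 15) {
  df <- x[!x$skipped & x$compartment == compartment, ]
  keep <- unique(df$parameter)[seq_len(min(top_n, length(unique(df$parameter))))]
  df <- df[df$parameter %in% keep, ]
  df$parameter <- factor(df$parameter, levels = rev(keep))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[metric]], y = .data$parameter,
                                   fill = factor(.data$perturbation))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = paste0(metric, " (%)"), y = NULL,
                  fill = "perturbation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
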