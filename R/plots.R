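# autoplot methods. Network layout drawing is deliberately out of scope
# (exports feed dedicated graph viewers); the network autoplot shows the
# degree structure instead.

#' @exportS3Method ggplot2::autoplot
autoplot.icf_tbl <- function(object, ...) {
  df <- object[!is.na(object$icf), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$disorder, .data$icf), y = .data$icf
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$icf_display)),
                       hjust = -0.15, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "Informant consensus factor",
                  title = "Informant consensus by ailment category")
}

#' @exportS3Method ggplot2::autoplot
autoplot.fl_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$disorder, y = .data$fl, colour = .data$kind
  )) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Fidelity level (%)", colour = "Kind",
                  title = "Fidelity levels by ailment category")
}

#' @exportS3Method ggplot2::autoplot
autoplot.icf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$concentration,
                                       y = .data$mean_icf)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_icf - .data$sd_icf,
                                      ymax = .data$mean_icf + .data$sd_icf),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dirichlet concentration (log scale)",
                  y = "Mean ICF",
                  title = "Consensus vs concentration in simulated surveys")
}

#' @exportS3Method ggplot2::autoplot
autoplot.ethno_network <- function(object, ...) {
  deg <- species_degree(object)
  ggplot2::ggplot(deg, ggplot2::aes(x = factor(.data$degree),
                                    fill = .data$kind)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Disorders treated (species degree)",
                  y = "Number of species", fill = "Kind",
                  title = "Degree distribution of the species mode")
}
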