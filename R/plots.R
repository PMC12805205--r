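# ggplot2 methods for the two result types.

#' Plot a reliability analysis
#'
#' Point-and-interval display of each coefficient with its Wald CI,
#' facetted by statistic type.
#'
#' @param object A `reliability_analysis` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reliability_analysis <- function(object, ...) {
  tab <- object$table
  tab$label <- ifelse(is.na(tab$item), tab$coefficient,
                      paste0(tab$coefficient, "[", tab$item, "]"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                             na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free") +
    ggplot2::labs(x = "estimate (Wald CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reliability_analysis
#' @export
plot_reliability <- function(object, ...) autoplot.reliability_analysis(object, ...)

#' Plot coverage from a simulation study
#'
#' Coverage per coefficient/target/method with the Agresti-Coull band; the
#' dashed line marks the nominal level.
#'
#' @param object An `se_study` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.se_study <- function(object, ...) {
  r <- object$results
  r$cell <- paste(r$coefficient, r$target, sep = ":")
  ggplot2::ggplot(r, ggplot2::aes(x = .data$coverage, y = .data$cell,
                                  colour = .data$method)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$band_lower,
                                         xmax = .data$band_upper),
                            colour = "grey70", height = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 100 * object$level, linetype = "dashed") +
    ggplot2::labs(x = "coverage (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.se_study
#' @export
plot_coverage <- function(object, ...) autoplot.se_study(object, ...)
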