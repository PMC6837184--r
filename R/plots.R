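#' Plot a ccdf on log-log axes
#'
#' @param object A [ccdf()] table.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cohsi_ccdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "value", y = "P(X ≥ x)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted power-law tail over the empirical ccdf
#'
#' @param object A [fit_power_tail()] object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cohsi_powerlaw <- function(object, ...) {
  cc <- ccdf(object$values)
  xs <- cc$x[cc$x >= object$xmin]
  scale_p <- cc$p[match(min(xs), cc$x)]
  theo <- tibble::tibble(
    x = xs,
    p = scale_p * hurwitz_zeta(object$exponent, xs) /
      hurwitz_zeta(object$exponent, object$xmin)
  )
  autoplot(cc) +
    ggplot2::geom_line(data = theo, colour = "red") +
    ggplot2::geom_vline(xintercept = object$xmin, linetype = "dashed") +
    ggplot2::labs(subtitle = sprintf("xmin = %g, exponent = %.3f", object$xmin, object$exponent))
}

#' Plot a homogeneous rank solution (Zipf line with droop)
#'
#' @param object A [solve_hom()] solution.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cohsi_rank_solution <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$count)),
                  ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot the heterogeneous solution locus against its power-law asymptote
#'
#' Log-log view of the full implicit solution (points) with the pure
#' power-law asymptote (line) and the physical boundary `t = a`.
#'
#' @param full Locus from [solve_het_locus()].
#' @param pure Asymptote from [pure_power_locus()].
#' @return A ggplot.
#' @export
plot_locus <- function(full, pure) {
  ggplot2::ggplot(dplyr::filter(full, .data$primary),
                  ggplot2::aes(x = .data$a, y = .data$t)) +
    ggplot2::geom_line(data = pure, colour = "darkgreen") +
    ggplot2::geom_point(colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "blue", linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "unique alphabet a", y = "length t") +
    ggplot2::theme_minimal()
}
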