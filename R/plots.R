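#' Divergence against species age (or any predictor)
#'
#' Scatter of each clade's average genetic divergence against a chosen
#' predictor, optionally with residual axes: when `partial_on` is given,
#' both axes are replaced by their residuals from ordinary regressions on
#' those covariates, the usual added-variable view for showing an age
#' effect net of geographic distance.
#'
#' @param clade_summary Tibble with at least `clade`, `avg_divergence`, and
#'   the chosen predictor.
#' @param x Predictor column name (default `"age"`).
#' @param partial_on Optional character vector of covariate columns to
#'   partial out of both axes.
#' @return A ggplot object.
#' @export
plot_divergence_age <- function(clade_summary, x = "age", partial_on = NULL) {
  stopifnot(is.data.frame(clade_summary), x %in% names(clade_summary))
  df <- clade_summary
  xlab <- x; ylab <- "avg_divergence"
  if (!is.null(partial_on)) {
    fx <- stats::reformulate(partial_on, x)
    fy <- stats::reformulate(partial_on, "avg_divergence")
    df$.x <- stats::resid(stats::lm(fx, df))
    df$.y <- stats::resid(stats::lm(fy, df))
    xlab <- paste(x, "| residual"); ylab <- "avg_divergence | residual"
  } else {
    df$.x <- df[[x]]; df$.y <- df$avg_divergence
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.x, y = .data$.y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a PGLS fit
#'
#' Point estimates with approximate 95% Wald intervals, intercept omitted.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(lo = .data$estimate - 1.96 * .data$std.error,
                  hi = .data$estimate + 1.96 * .data$std.error)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::labs(x = "estimate (95% Wald)", y = NULL) +
    ggplot2::theme_minimal()
}
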