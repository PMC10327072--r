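#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: a forest plot of a
#' coefficient table, per-level coefficient trajectories of a signature
#' scan, and the loss surface of a grid fit. `plot_rt_by_value()` shows
#' the behavioral pattern at the heart of the design: per-condition RT as
#' a function of overall value.
#'
#' @param object A `coef_table`, `lca_signature` or `lca_grid_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name choicelca-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname choicelca-plots
#' @export
autoplot.coef_table <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$estimate) & d$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term,
                                                     .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname choicelca-plots
#' @export
autoplot.lca_signature <- function(object, ...) {
  d <- object$coefficients
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$level),
                                  y = .data$estimate, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std.error,
                   ymax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = object$manipulate, y = "estimate") +
    ggplot2::theme_minimal()
}

#' @rdname choicelca-plots
#' @export
autoplot.lca_grid_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$loss)
  vars <- setdiff(names(d), "loss")
  if (length(vars) >= 2) {
    ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[vars[1]]]),
                                    y = factor(.data[[vars[2]]]),
                                    fill = .data$loss)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(direction = -1) +
      ggplot2::labs(x = vars[1], y = vars[2], fill = "loss") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[vars[1]]], y = .data$loss)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::theme_minimal()
  }
}

#' @rdname choicelca-plots
#' @param trials A trial table with `rt`, `ov`, `condition`, `omitted`.
#' @export
plot_rt_by_value <- function(trials) {
  d <- dplyr::filter(tibble::as_tibble(trials), !.data$omitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ov, y = .data$rt,
                                  colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "overall value", y = "RT (s)", colour = NULL) +
    ggplot2::theme_minimal()
}
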