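#' Plot a simulation report
#'
#' Rejection rates against the injected effect size, one line per method,
#' faceted by outcome and scenario, with 2-SE Monte-Carlo error bars.
#' Null (type-I error) rows are drawn at `delta = 0` together with a dashed
#' line at the nominal level.
#'
#' @param object A `sim_report` from [estimate_type1()],
#'   [estimate_power()] or [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_report
#' @export
autoplot.sim_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  alpha <- df$alpha[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$rate,
                                   colour = .data$method)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$rate - 2 * .data$mc_se),
      ymax = pmin(1, .data$rate + 2 * .data$mc_se))) +
    ggplot2::facet_grid(.data$outcome ~ .data$scenario) +
    ggplot2::labs(x = "injected effect size (delta)",
                  y = "rejection rate",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot the rank-based longitudinal profiles of one period
#'
#' Relative-effect profiles over time for the two treatment groups -- the
#' quantity whose group-by-time interaction the ANOVA-type statistic tests.
#'
#' @param object An `ats_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ats_result
#' @export
autoplot.ats_result <- function(object, ...) {
  ggplot2::ggplot(object$rel_effects,
                  ggplot2::aes(x = .data$time, y = .data$rel_effect,
                               colour = .data$treatment)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time point", y = "relative effect",
                  title = sprintf("Period %d (%s): ATS p = %.3g",
                                  object$period, object$outcome,
                                  object$p_value)) +
    ggplot2::theme_bw()
}

#' Plot Akaike weights of a model-averaging result
#'
#' @param object An `ma_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ma_result
#' @export
autoplot.ma_result <- function(object, ...) {
  df <- tibble::as_tibble(object$table)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$model_id,
                                                      .data$weight),
                                   y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Akaike weight") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
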