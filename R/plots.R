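#' Forest plot of a multiple contrast test
#'
#' Plots the per-contrast effect estimates with their simultaneous
#' confidence intervals against the null value (0 for contrast effects,
#' 1/2 for pairwise relative effects).
#'
#' @param object A `moi_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moi_test
#' @export
#' @importFrom ggplot2 autoplot
autoplot.moi_test <- function(object, ...) {
  tab <- tidy(object)
  tab$contrast <- factor(tab$contrast, levels = rev(tab$contrast))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = object$null_value, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = if (object$ranking == "pairwise") "relative effect" else "effect difference",
      y = NULL,
      title = sprintf("%s contrasts (%s ranking), %d%% simultaneous intervals",
                      object$contrast_type, object$ranking,
                      round(100 * (1 - object$alpha)))
    ) +
    ggplot2::theme_minimal()
}

#' Rejection-rate plot of a simulation study
#'
#' Bar chart of empirical rejection rates per method with Monte-Carlo
#' error bars and the nominal level marked; a type-I error plot when
#' `h2 = 0`, a power plot otherwise.
#'
#' @param object A `moi_study` tibble from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moi_study
#' @export
autoplot.moi_study <- function(object, ...) {
  what <- if (all(object$h2 == 0)) "type-I error" else "power"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - 2 * .data$mc_se,
                                        ymax = .data$rate + 2 * .data$mc_se),
                           width = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = sprintf("empirical %s", what)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
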