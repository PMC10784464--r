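#' Plot cross-validation predictive abilities
#'
#' One point (mean Pearson r) with an error bar (+- one standard error) per
#' environment and method, faceted by validation scenario — the usual way
#' predictive-ability comparisons across CV1/CV2 scenarios are displayed.
#'
#' @param object A `cv_ability` table from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_ability <- function(object, ...) {
  ggplot(object, aes(x = .data$environment, y = .data$mean_r,
                     colour = .data$method, group = .data$method)) +
    geom_point(position = position_dodge(width = 0.5), size = 2) +
    geom_errorbar(aes(ymin = .data$mean_r - .data$se_r,
                      ymax = .data$mean_r + .data$se_r),
                  position = position_dodge(width = 0.5), width = 0.25) +
    facet_wrap(~scenario) +
    labs(x = "environment", y = "predictive ability (Pearson r)",
         colour = "method") +
    theme_minimal()
}

#' Plot variance components of a GBLUP fit
#'
#' @param object A `gblup_fit`.
#' @param ... Unused.
#' @return A ggplot object (bar chart of the estimated components).
#' @export
autoplot.gblup_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$term, y = .data$estimate)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "estimate",
         title = sprintf("GBLUP-%s variance components (logL = %.2f)",
                         object$model, object$logL)) +
    theme_minimal()
}
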