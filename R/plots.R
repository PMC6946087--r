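#' Covariate effect plot (point estimates with 95% intervals)
#'
#' Standardized (per-SD) environmental effects on annual log biomass, one
#' point per reported taxon-covariate model, with approximate 95%
#' intervals (`+-1.96 SE`).
#'
#' @param selection_table selection table from [run_pipeline()] (or any
#'   data frame with `taxon`, `covariate`, `beta2`, `beta2_se`).
#' @return a ggplot object.
#' @importFrom ggplot2 .data
#' @export
plot_covariate_effects <- function(selection_table) {
  d <- selection_table[!is.na(selection_table$beta2), , drop = FALSE]
  d$lo <- d$beta2 - 1.96 * d$beta2_se
  d$hi <- d$beta2 + 1.96 * d$beta2_se
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta2,
                                  y = paste(.data$taxon, .data$covariate),
                                  colour = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = "effect on annual log biomass (per SD of covariate)",
                  y = NULL, colour = "covariate") +
    ggplot2::theme_minimal()
}

#' Wind effect plot by sampling method
#'
#' Day-level wind effects (per SD of daily mean wind) on sampled log
#' biomass, separately for integrated and ferrybox sampling, with 95%
#' intervals.
#'
#' @param wind_table wind table from [run_pipeline()] (columns `taxon`,
#'   `term`, `estimate`, `se`).
#' @return a ggplot object.
#' @export
plot_wind_effects <- function(wind_table) {
  d <- wind_table[wind_table$term %in% c("wind_ferrybox", "wind_integrated"), ,
                  drop = FALSE]
  d$method <- ifelse(d$term == "wind_integrated", "integrated", "ferrybox")
  d$lo <- d$estimate - 1.96 * d$se
  d$hi <- d$estimate + 1.96 * d$se
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$taxon,
                                  colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_colour_manual(values = c(integrated = "black",
                                            ferrybox = "grey55")) +
    ggplot2::labs(x = "wind effect on sampled log biomass (per SD)",
                  y = NULL, colour = "method") +
    ggplot2::theme_minimal()
}
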