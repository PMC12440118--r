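#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the estimated ITE distribution
#'
#' Histogram of per-subject ITE estimates, filled by the resulting
#' treatment recommendation, with the decision boundary at zero.
#'
#' @param object a `survite_ite` object.
#' @param bins histogram bins.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.survite_ite <- function(object, bins = 50, ...) {
  ggplot2::ggplot(object$ite, ggplot2::aes(x = .data$theta_hat,
                                           fill = .data$recommendation)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression(hat(theta)(t^"*")),
      y = "subjects",
      fill = "recommendation",
      title = paste0(object$meta, " / ", object$base_learner,
                     " ITE at t* = ", signif(object$horizon, 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot Boruta hit rates by decision
#'
#' @param object a `boruta_result`.
#' @param ... unused.
#' @return A ggplot of per-feature hit fractions coloured by decision.
#' @export
autoplot.boruta_result <- function(object, ...) {
  df <- dplyr::mutate(object$result,
                      hit_rate = ifelse(.data$iterations > 0,
                                        .data$hits / .data$iterations, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data$hit_rate),
                                   y = .data$hit_rate, fill = .data$decision)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "hit fraction", fill = "decision") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier cohort treatment effects
#'
#' Bar chart of the KM-difference treatment effect within the RT and RC
#' cohorts and overall, as produced by [km_cohort_effect()].
#'
#' @param effects tibble from [km_cohort_effect()].
#' @return A ggplot.
#' @export
plot_km_cohort <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$cohort, y = .data$effect,
                                        fill = .data$cohort)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "KM(treated) - KM(control) at t*") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
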