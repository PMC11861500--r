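#' Plot a time-dependent ROC curve
#' @param object a [time_dependent_roc()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.td_roc <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Time-dependent ROC at t = %g (AUC = %.3f)",
                      object$horizon, object$auc)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by risk group
#' @param time,event survival outcome.
#' @param group group label per sample.
#' @return a ggplot of the stepped survival curves.
#' @export
plot_km <- function(time, event, group) {
  dfs <- lapply(split(seq_along(time), group), function(idx) {
    km <- km_estimate(time[idx], event[idx])
    km$group <- group[idx[1]]
    dplyr::bind_rows(tibble::tibble(time = 0, surv = 1, group = km$group[1]),
                     km[, c("time", "surv", "group")])
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", color = "Group") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#' @param assignment a [module_trait_statistics()] result.
#' @return a ggplot tile map of module-trait correlations.
#' @export
plot_module_trait <- function(assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  df <- assignment$module_trait
  ggplot2::ggplot(df, ggplot2::aes(.data$trait, .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(p=%.1e)", .data$r, .data$p)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Calibration plot of nomogram-predicted vs observed survival
#' @param calibration a [calibration_curve()] table.
#' @return a ggplot with the identity line for reference.
#' @export
plot_calibration <- function(calibration) {
  df <- calibration[!calibration$flagged, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(x = "Predicted survival", y = "Observed (KM) survival") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
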