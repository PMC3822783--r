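#' Plot a homeostasis trajectory
#'
#' Total, resting and dividing cell numbers against time, log10 y-scale.
#'
#' @param object A `cd4_trajectory` from [simulate_homeostasis()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cd4_trajectory
#' @export
autoplot.cd4_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_days", "X_cells",
                  "Y_cells", "N_cells"),
    cols = -"time_days", names_to = "compartment", values_to = "cells"
  )
  long$compartment <- factor(long$compartment,
                             levels = c("N_cells", "X_cells", "Y_cells"),
                             labels = c("total", "resting", "dividing"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$cells,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "cells", colour = NULL,
                  title = "Naive CD4 homeostasis trajectory")
}

#' Plot the dividing:resting ratio of a trajectory
#'
#' @param traj A `cd4_trajectory`.
#' @return A ggplot object.
#' @export
plot_ratio <- function(traj) {
  stopifnot(inherits(traj, "cd4_trajectory"))
  ggplot2::ggplot(traj, ggplot2::aes(.data$time_days, .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "dividing : resting ratio (Y/X)")
}

#' Plot the pediatric concentration prediction
#'
#' @param object A `cd4_childhood` from [simulate_childhood()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cd4_childhood
#' @export
autoplot.cd4_childhood <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$age_years,
                                       .data$concentration_cells_per_ul)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (years)", y = "naive CD4 (cells/µl)",
                  title = "Predicted blood naive CD4 concentration")
}

#' Plot a synthetic cohort against the model prediction
#'
#' @param cohort A `cd4_cohort` from [generate_cohort()].
#' @param predicted Optional `cd4_childhood` curve to overlay.
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, predicted = NULL) {
  g <- ggplot2::ggplot(cohort,
                       ggplot2::aes(.data$age_years,
                                    .data$naive_cd4_cells_per_ul)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "age (years)", y = "naive CD4 (cells/µl)")
  if (!is.null(predicted)) {
    g <- g + ggplot2::geom_line(
      data = predicted,
      ggplot2::aes(.data$age_years, .data$concentration_cells_per_ul),
      colour = "firebrick", linewidth = 1
    )
  }
  g
}
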