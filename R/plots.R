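#' Plot group recovery trajectories
#'
#' Median daily composite per group with an interquartile ribbon, the
#' standard presentation for the 0-18 recovery score across post-operative
#' days.
#'
#' @param trajectories Tibble with `group`, `day`, `total` (see
#'   [build_trajectories()]).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  autoplot(group_trajectory_summary(trajectories))
}

#' @rdname plot_trajectories
#' @param object A `qor_traj_summary` from [group_trajectory_summary()].
#' @param ... Unused.
#' @export
autoplot.qor_traj_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$day, y = .data$median,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 18),
                                breaks = seq(0, 18, by = 3)) +
    ggplot2::labs(x = "Post-operative day",
                  y = "Quality-of-recovery composite (0-18)",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot a von Frey staircase session
#'
#' Trial-by-trial filament forces on a log scale, marking withdrawal
#' responses.
#'
#' @param session A [vf_session()].
#' @return A ggplot object.
#' @export
plot_staircase <- function(session) {
  d <- session$trials |>
    mutate(trial = dplyr::row_number(),
           outcome = ifelse(.data$response, "response", "no response"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$force_g)) +
    ggplot2::geom_step(direction = "hv", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outcome), size = 3) +
    ggplot2::scale_y_log10(breaks = signif(session$filament_set, 2)) +
    ggplot2::scale_shape_manual(values = c(response = 16,
                                           `no response` = 1)) +
    ggplot2::labs(x = "Trial", y = "Filament force (g)", shape = NULL) +
    ggplot2::theme_minimal()
}
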