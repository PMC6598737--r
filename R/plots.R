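#' Spaghetti plot of observed longitudinal data
#'
#' One line per subject, anchored at the baseline visit, facetted by
#' biomarker.
#'
#' @param table Cohort tibble with `subject_id`, `years_since_baseline`
#'   and biomarker columns.
#' @param biomarkers Biomarker columns to show.
#' @return A ggplot object.
#' @export
plot_spaghetti <- function(table, biomarkers) {
  long <- table |>
    select("subject_id", "years_since_baseline", all_of(biomarkers)) |>
    pivot_longer(all_of(biomarkers), names_to = "biomarker",
                 values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$years_since_baseline,
                                     y = .data$value,
                                     group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::facet_wrap(~biomarker, scales = "free_y") +
    ggplot2::labs(x = "Years since baseline", y = "Value") +
    ggplot2::theme_minimal()
}

#' Plot anchored DEM trajectories, optionally with a staging histogram
#'
#' @param trajectories Named list of anchored `progmod_trajectory`
#'   objects.
#' @param staging Optional [stage_subjects_dem()] tibble; shown as a
#'   histogram of subject stage times under the curves.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, staging = NULL) {
  long <- purrr::imap(trajectories, function(tr, b) {
    tibble(biomarker = b, time = tr$time, z = tr$z)
  }) |> list_rbind()
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$z,
                                          colour = .data$biomarker)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Years since t0", y = "Z-score relative to controls",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(staging) && nrow(staging)) {
    ymin <- min(long$z, na.rm = TRUE)
    p <- p + ggplot2::geom_histogram(
      data = staging,
      ggplot2::aes(x = .data$stage_time,
                   y = ggplot2::after_stat(!!quote(density)) * abs(ymin) / 2),
      inherit.aes = FALSE, bins = 25, alpha = 0.35, fill = "grey40",
      boundary = 0)
  }
  p
}

#' Hairy-line plot: subjects anchored on the group trajectory
#'
#' Each subject's observed series is shifted in time so that its baseline
#' value sits on the group trajectory at the subject's staged time.
#'
#' @param table Cohort tibble (z-scored and oriented like the trajectory).
#' @param biomarker Biomarker column.
#' @param trajectory Anchored `progmod_trajectory` for that biomarker.
#' @param staging [stage_subjects_dem()] tibble giving each subject's
#'   `stage_time`.
#' @return A ggplot object.
#' @export
plot_hairy_lines <- function(table, biomarker, trajectory, staging) {
  long <- table |>
    select("subject_id", "years_since_baseline", value = all_of(biomarker)) |>
    inner_join(staging |> select("subject_id", "stage_time"),
               by = "subject_id") |>
    mutate(time = .data$stage_time + .data$years_since_baseline)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = tidy(trajectory),
                       ggplot2::aes(x = .data$time, y = .data$z),
                       linewidth = 1, colour = "black") +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(x = .data$time, y = .data$value,
                                    group = .data$subject_id),
                       alpha = 0.3, colour = "steelblue") +
    ggplot2::labs(x = "Years since t0", y = "Z-score", title = biomarker) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trajectories autoplot method for a single trajectory.
#' @param object,... Trajectory and ignored arguments.
#' @export
autoplot.progmod_trajectory <- function(object, ...) {
  d <- tidy(object)
  y <- if (object$anchored) "z" else "value"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data[[y]])) +
    ggplot2::geom_line(linewidth = 0.9, colour = "darkgreen") +
    ggplot2::labs(x = if (object$anchored) "Years since t0" else "Years",
                  y = if (object$anchored) "Z-score" else "Value") +
    ggplot2::theme_minimal()
}

#' Autoplot a GP rate-of-change model
#'
#' Subject slope points with the posterior mean rate and 95% band.
#'
#' @param object A `progmod_rate_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progmod_rate_model <- function(object, ...) {
  band <- tidy(object)
  pts <- tibble(value = object$x, slope = object$y)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "palegreen3", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate), colour = "darkgreen") +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$slope),
                        shape = 4, alpha = 0.6) +
    ggplot2::labs(x = "Biomarker value", y = "Rate of change (units/year)") +
    ggplot2::theme_minimal()
}

#' Autoplot a positional variance diagram
#'
#' Heatmap of `P(event at position)`; darker shades mean higher
#' probability, events ordered by their modal position.
#'
#' @param object A `progmod_posvar`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progmod_posvar <- function(object, ...) {
  d <- tidy(object)
  ord <- d |>
    group_by(.data$biomarker) |>
    summarise(mp = sum(.data$position * .data$probability), .groups = "drop") |>
    arrange(dplyr::desc(.data$mp))
  d$biomarker <- factor(d$biomarker, levels = ord$biomarker)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$biomarker,
                                  fill = .data$probability)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Position in sequence", y = NULL,
                  fill = "P(event)") +
    ggplot2::theme_minimal()
}

#' Autoplot a mixture fit
#'
#' @param object A `progmod_mixture`.
#' @param range,n Passed to [tidy.progmod_mixture()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progmod_mixture <- function(object, range = NULL, n = 200, ...) {
  d <- tidy(object, range = range, n = n) |>
    pivot_longer(c("density_normal", "density_abnormal"),
                 names_to = "component", values_to = "density")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$density,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = object$biomarker, colour = NULL) +
    ggplot2::theme_minimal()
}
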