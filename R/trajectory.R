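#' Build per-animal recovery trajectories
#'
#' Arranges daily composites into ordered (day, total) series per animal and,
#' by default, prepends the baseline point. At day 0 every domain equals its
#' own baseline by construction, so every %MPE is 0 and the composite is
#' exactly 18; trajectories therefore start at (0, 18) unless day-0
#' composites are already present.
#'
#' @param composites Output of [daily_composites()].
#' @param include_baseline Prepend (0, 18) per animal when day 0 is absent.
#' @return Tibble with columns `animal_id`, `group`, `day`, `total`, ordered
#'   by animal and day.
#' @export
build_trajectories <- function(composites, include_baseline = TRUE) {
  req <- c("animal_id", "group", "day", "total")
  missing_cols <- setdiff(req, names(composites))
  if (length(missing_cols)) {
    abort(paste0("Composite table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- composites |> select(all_of(req))
  if (include_baseline) {
    base <- out |>
      distinct(.data$animal_id, .data$group) |>
      anti_join(out |> filter(.data$day == 0),
                by = c("animal_id", "group")) |>
      mutate(day = 0, total = 18L)
    out <- bind_rows(out, base)
  }
  out |> arrange(.data$animal_id, .data$day) |> as_tibble()
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Trajectory area under the curve
#'
#' Trapezoidal area under each animal's (day, composite) trajectory over the
#' observed window, with no extrapolation beyond it. A constant score `c`
#' over a span of `T` days gives `c * T` score-days: a naive-like animal
#' holding 17 points across days 0-6 scores an AUC of 102. Lower area means
#' worse overall recovery.
#'
#' @param trajectories Tibble with columns `day` and `total`, and optionally
#'   `animal_id`/`group` (see [build_trajectories()]); a single unlabeled
#'   trajectory is also accepted.
#' @return Tibble with one row per animal: `animal_id`, `group` (if
#'   present), `auc` (score-days), `n_days`.
#' @export
#' @examples
#' trajectory_auc(tibble::tibble(day = c(0, 1, 2, 3, 6), total = 17))
trajectory_auc <- function(trajectories) {
  if (!all(c("day", "total") %in% names(trajectories))) {
    abort("Trajectories need columns day and total.")
  }
  if (!"animal_id" %in% names(trajectories)) {
    trajectories <- trajectories |> mutate(animal_id = "animal_1")
  }
  if (!"group" %in% names(trajectories)) {
    trajectories <- trajectories |> mutate(group = NA_character_)
  }
  short <- trajectories |>
    count(.data$animal_id) |>
    filter(.data$n < 2)
  if (nrow(short)) {
    abort(paste0("Insufficient trajectory (fewer than 2 points) for: ",
                 paste(short$animal_id, collapse = ", ")))
  }
  trajectories |>
    arrange(.data$animal_id, .data$day) |>
    summarise(auc = trapezoid_area(.data$day, .data$total),
              n_days = n(),
              .by = c("animal_id", "group"))
}

#' Per-group trajectory summary
#'
#' Median and interquartile range of the composite per group and day
#' (sample quantiles with linear interpolation, R's default type 7), matching
#' the median-with-IQR presentation used for nonparametric endpoints.
#'
#' @param trajectories Tibble with `group`, `day`, `total` (see
#'   [build_trajectories()]).
#' @return Tibble of class `qor_traj_summary`: `group`, `day`, `n`,
#'   `median`, `q25`, `q75`.
#' @export
group_trajectory_summary <- function(trajectories) {
  req <- c("group", "day", "total")
  missing_cols <- setdiff(req, names(trajectories))
  if (length(missing_cols)) {
    abort(paste0("Trajectory table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(trajectories) == 0) abort("Empty trajectory table.")
  out <- trajectories |>
    summarise(n = n(),
              median = median(.data$total),
              q25 = quantile(.data$total, 0.25, names = FALSE),
              q75 = quantile(.data$total, 0.75, names = FALSE),
              .by = c("group", "day")) |>
    arrange(.data$group, .data$day)
  class(out) <- c("qor_traj_summary", class(out))
  out
}

#' Sample size for a two-sample comparison of composite scores
#'
#' Smallest group size for which a two-sided two-sample t-test at level
#' `alpha` detects a `reduction_fraction` drop from `mean_score` with the
#' requested power, found by ascending search over the exact
#' noncentral-t power (via [stats::power.t.test()]). With the planning
#' assumptions used in the study design (mean 17, SD 4, 50% reduction,
#' power 0.8) the calculation reports its own answer; it is not forced to
#' match any particular published group size.
#'
#' @param mean_score Assumed mean composite in the reference group.
#' @param sd_score Assumed common SD of the composite.
#' @param reduction_fraction Fractional reduction to detect, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param alpha Two-sided significance level.
#' @return Integer n per group (minimum 2).
#' @export
#' @examples
#' required_sample_size(17, 4, 0.5)
required_sample_size <- function(mean_score, sd_score, reduction_fraction,
                                 power = 0.8, alpha = 0.05) {
  if (reduction_fraction <= 0 || reduction_fraction >= 1) {
    abort("reduction_fraction must lie in (0, 1).")
  }
  if (power <= 0 || power >= 1) abort("power must lie in (0, 1).")
  if (sd_score <= 0 || mean_score <= 0) {
    abort("mean_score and sd_score must be positive.")
  }
  delta <- mean_score * reduction_fraction
  for (n in 2:100000) {
    pw <- power.t.test(n = n, delta = delta, sd = sd_score,
                       sig.level = alpha)$power
    if (pw >= power) return(as.integer(n))
  }
  abort("Infeasible parameters: no n up to 100000 reaches the target power.")
}

#' Repeated-measures ANOVA on composite trajectories
#'
#' Thin contract over [stats::aov()] for the time-by-treatment
#' repeated-measures analysis (subject as error stratum); the bespoke
#' machinery of this package is the score, the trajectory AUC and the
#' rank-based tests, so the parametric longitudinal model delegates to the
#' standard routine.
#'
#' @param trajectories Tibble with `animal_id`, `group`, `day`, `total`.
#' @return An `aov` object (summary via `summary()`).
#' @export
rm_anova <- function(trajectories) {
  d <- trajectories |>
    mutate(day_f = factor(.data$day),
           animal_id = factor(.data$animal_id),
           group = factor(.data$group))
  aov(total ~ group * day_f + Error(animal_id), data = d)
}
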