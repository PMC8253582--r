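# Long-format measurement CSV dialect:
#   animal_id,group,day,domain,value,unit
# Day 0 is reserved for the baseline; raw files may instead carry the
# pre-operative observation days as negative days (-3, -2, -1), which are
# averaged into day 0 on read.

measurement_cols <- c("animal_id", "group", "day", "domain", "value", "unit")

#' Read and validate a long-format measurement CSV
#'
#' Schema-validates the measurement dialect (`animal_id`, `group`, `day`,
#' `domain`, `value`, `unit`): domains and units must match
#' [domain_units()], groups must be known labels, values must be
#' non-negative numbers, and `(animal_id, day, domain)` must be unique.
#' Error messages cite file line numbers (header = line 1). Negative days
#' encode pre-operative baseline measurements and are collapsed to their
#' per-animal, per-domain mean at day 0; a file providing both negative days
#' and an explicit day 0 for the same animal-domain is rejected.
#'
#' @param path CSV file path.
#' @param groups Permitted group labels.
#' @return Validated tibble of measurements with day 0 baselines.
#' @export
read_measurements <- function(path, groups = qor_groups()) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    group = readr::col_character(),
    day = readr::col_double(),
    domain = readr::col_character(),
    value = readr::col_double(),
    unit = readr::col_character())))
  probs <- readr::problems(raw)  # parse issues become structured errors
  if (nrow(probs)) {
    abort(paste0("Malformed value(s) at line(s) ",
                 paste(unique(probs$row), collapse = ", "),
                 " of ", path, "."))
  }
  missing_cols <- setdiff(measurement_cols, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw |> mutate(.line = dplyr::row_number() + 1)
  fail_lines <- function(bad, what) {
    if (nrow(bad)) {
      abort(paste0(what, " at line(s) ",
                   paste(bad$.line, collapse = ", "), "."))
    }
  }
  units <- domain_units()
  fail_lines(raw |> filter(!.data$domain %in% names(units)),
             "Unknown domain")
  fail_lines(raw |> filter(!.data$group %in% groups), "Unknown group")
  fail_lines(raw |> filter(.data$unit != units[.data$domain]),
             "Unit does not match domain")
  fail_lines(raw |> filter(is.na(.data$value) | .data$value < 0),
             "Missing or negative value")
  fail_lines(raw |> filter(.data$day != round(.data$day)),
             "Non-integer day")
  dup <- raw |>
    filter(.data$day >= 0) |>
    group_by(.data$animal_id, .data$day, .data$domain) |>
    filter(n() > 1) |>
    ungroup()
  fail_lines(dup, "Duplicate (animal_id, day, domain)")
  dup_pre <- raw |>
    group_by(.data$animal_id, .data$day, .data$domain) |>
    filter(n() > 1, .data$day < 0) |>
    ungroup()
  fail_lines(dup_pre, "Duplicate pre-operative day")
  both <- raw |>
    summarise(has0 = any(.data$day == 0), hasneg = any(.data$day < 0),
              .line = min(.data$.line),
              .by = c("animal_id", "domain")) |>
    filter(.data$has0 & .data$hasneg)
  if (nrow(both)) {
    abort(paste0("Baseline given both as day 0 and as pre-operative days ",
                 "for: ",
                 paste(paste0(both$animal_id, "/", both$domain),
                       collapse = ", "), "."))
  }
  baseline <- raw |>
    filter(.data$day < 0) |>
    summarise(value = mean(.data$value), day = 0,
              .by = c("animal_id", "group", "domain", "unit"))
  bind_rows(raw |> filter(.data$day >= 0) |> select(-".line"), baseline) |>
    select(all_of(measurement_cols)) |>
    mutate(day = as.integer(.data$day)) |>
    arrange(.data$group, .data$animal_id, .data$day, .data$domain)
}

#' Write measurements to CSV
#'
#' Inverse of [read_measurements()] for day >= 0 records; a read of the
#' written file reproduces the table exactly.
#'
#' @param measurements Measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements |> select(all_of(measurement_cols)), path)
  invisible(path)
}

#' Read a von Frey trial-level CSV
#'
#' One row per staircase trial: `animal_id`, `day`, `trial_index`,
#' `force_g`, `response` (0/1 or logical), ordered by trial within each
#' animal-day.
#'
#' @param path CSV file path.
#' @return Validated tibble of trials.
#' @export
read_vonfrey_trials <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    day = readr::col_double(),
    trial_index = readr::col_double(),
    force_g = readr::col_double(),
    response = readr::col_logical())))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(paste0("Malformed value(s) at line(s) ",
                 paste(unique(probs$row), collapse = ", "),
                 " of ", path, "."))
  }
  if (anyNA(raw)) abort("Trial files may not contain missing values.")
  if (any(raw$force_g <= 0)) abort("Filament forces must be positive.")
  raw
}

#' Pipeline run configuration
#'
#' Bundles every option of the paper-faithful pipeline; the defaults
#' reproduce it exactly. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param anchors Maximum-deficit anchors ([deficit_anchors()]).
#' @param orientation Domain-score bin orientation ([domain_score()]).
#' @param filament_set Von Frey filament forces ([default_filaments()]).
#' @param auc_window Days spanned by the trajectory AUC (inclusive).
#' @param posthoc_adjust Multiplicity adjustment for [dunn_posthoc()].
#' @param seed Seed for any simulation stage.
#' @param outdir Output directory for [run_pipeline()].
#' @return Named list of class `run_config`.
#' @export
run_config <- function(anchors = deficit_anchors(),
                       orientation = "inverted",
                       filament_set = default_filaments(),
                       auc_window = c(0, 6),
                       posthoc_adjust = "holm",
                       seed = 1,
                       outdir = ".") {
  cfg <- list(anchors = anchors, orientation = orientation,
              filament_set = filament_set, auc_window = auc_window,
              posthoc_adjust = posthoc_adjust, seed = as.integer(seed),
              outdir = outdir)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$anchors <- as.list(x$anchors)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(anchors = deficit_anchors()[] |>
               (\(a) {a[names(x$anchors)] <- unlist(x$anchors); a})(),
             orientation = x$orientation,
             filament_set = as.numeric(x$filament_set),
             auc_window = as.numeric(x$auc_window),
             posthoc_adjust = x$posthoc_adjust,
             seed = x$seed,
             outdir = x$outdir)
}
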