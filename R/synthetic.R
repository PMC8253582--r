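#' Specify a simulated cohort
#'
#' @param groups Group labels, a subset of [qor_groups()].
#' @param n_per_group Animals per group (study design used 6).
#' @param days Strictly increasing observation days; must include day 0
#'   (baseline). Default matches the study design: baseline plus
#'   post-operative days 1, 2, 3 and 6.
#' @param seed RNG seed; the same spec yields a bit-identical cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = qor_groups(), n_per_group = 6,
                        days = c(0, 1, 2, 3, 6), seed = 1) {
  unknown <- setdiff(groups, qor_groups())
  if (length(unknown)) {
    abort(paste0("Unknown group label(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(groups) == 0) abort("At least one group is required.")
  if (n_per_group < 1) abort("n_per_group must be at least 1.")
  if (any(diff(days) <= 0)) abort("days must be strictly increasing.")
  if (!0 %in% days) abort("days must include the baseline day 0.")
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 days = as.numeric(days), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Per-domain generative models
#'
#' One row per behavioral domain: the healthy (baseline) distribution and the
#' laparotomy day-1 deficit calibration. `healthy_mean`/`healthy_sd` are mean
#' and SD for truncated-normal domains; for the strictly positive log-normal
#' domains (`transit_min`, `vonfrey_g`) they are the median and the SD on the
#' log10 scale. `deficit_magnitude` is the fraction of the distance from
#' baseline to the maximum-deficit anchor reached on post-operative day 1 by
#' an untreated laparotomy animal; group effects rescale it (see
#' [group_effects()]).
#'
#' Healthy centers and the deficit fractions are calibrated once against the
#' published day-1 group medians (food 17.25 vs 6.75 g; transit 72.5 vs 617
#' min; von Frey 1.2 vs 0.28 g; distance 271.2 vs 138.9 m); spreads derive
#' loosely from the published interquartile ranges.
#'
#' @return Tibble with columns `domain`, `healthy_mean`, `healthy_sd`,
#'   `deficit_magnitude`, `noise` (`"normal"` or `"lognormal"`), `scored`.
#' @export
domain_models <- function() {
  tibble(
    domain = c("food_g", "transit_min", "sucrose_pref_pct", "vonfrey_g",
               "distance_m", "social_s", "water_ml", "weight_g"),
    healthy_mean = c(17.25, 72.5, 85, 1.2, 271.2, 60, 30, 375),
    healthy_sd = c(2.0, 0.19, 7, 0.25, 39.5, 10, 4, 25),
    deficit_magnitude = c(0.609, 0.841, 0.20, 0.793, 0.773, 0.30, 0.45, 1),
    noise = c("normal", "lognormal", "normal", "lognormal", "normal",
              "normal", "normal", "normal"),
    scored = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
}

#' Group-level recovery kinetics
#'
#' The latent deficit of an animal in group `g` on post-operative day `t >= 1`
#' is `d(t) = s_g * m * exp(-r_g * (t - 1))`, where `m` is the domain's
#' day-1 laparotomy deficit fraction, `s_g` the group's deficit scale and
#' `r_g` its recovery rate per day; `d(0) = 0` at baseline. Controls have
#' scale 0 (naive) or a small transient day-1 dip (sham); treatments reduce
#' the day-1 deficit and alter the recovery rate (aspirin slows late
#' recovery, aspirin + EPA accelerates it), mirroring the published ordering
#' of the treatment arms.
#'
#' @return Tibble with columns `group`, `deficit_scale`, `recovery_rate`.
#' @export
group_effects <- function() {
  tibble(
    group = qor_groups(),
    deficit_scale = c(0, 0.2, 1, 0.6, 0.6),
    recovery_rate = c(0, 1, 0.5, 0.25, 0.8))
}

#' Zero-effect group kinetics
#'
#' All groups share the healthy distribution (deficit scale 0); used for
#' type-I error calibration, where group labels must be exchangeable.
#'
#' @return Tibble like [group_effects()] with all deficit scales 0.
#' @export
null_group_effects <- function() {
  group_effects() |> mutate(deficit_scale = 0)
}

#' Latent deficit trajectory
#'
#' @param day Day(s) since surgery (0 = baseline).
#' @param magnitude Day-1 deficit fraction in `[0, 1]`.
#' @param rate Exponential recovery rate per day, >= 0.
#' @return Deficit fraction(s): 0 at baseline, `magnitude * exp(-rate *
#'   (day - 1))` thereafter. Non-increasing in `day` for positive rates.
#' @export
latent_deficit <- function(day, magnitude, rate) {
  if (any(magnitude < 0 | magnitude > 1)) {
    abort("deficit magnitude must lie in [0, 1].")
  }
  if (any(rate < 0)) abort("recovery rate must be non-negative.")
  ifelse(day < 1, 0, magnitude * exp(-rate * (day - 1)))
}

#' Simulate a cohort of animals
#'
#' Generates long-format behavioral measurements for every animal, domain and
#' day in the spec, together with the latent truth used to generate them.
#' Post-operative expected values move from the animal's healthy center
#' toward the domain's maximum-deficit anchor by the latent deficit fraction,
#' then recover exponentially; observations add truncated-normal or
#' log-normal noise per [domain_models()]. The day-0 baseline for food and
#' water intake is the mean of three simulated pre-operative days (the
#' protocol averages intake over the three days before surgery); other
#' domains use a single pre-operative measurement. Body weight follows a
#' growth path (+0.8%/day) that the latent deficit stalls.
#'
#' @param spec A [cohort_spec()].
#' @param models Per-domain models, see [domain_models()].
#' @param effects Group kinetics, see [group_effects()];
#'   [null_group_effects()] gives exchangeable groups.
#' @param anchors Maximum-deficit anchors, see [deficit_anchors()].
#' @return Object of class `sim_cohort`: a list with `measurements` (tibble:
#'   `animal_id`, `group`, `day`, `domain`, `value`, `unit`) and `truth`
#'   (tibble: per animal-domain-day latent deficit and noise-free expected
#'   value, including each animal's true von Frey threshold path), plus the
#'   generating `spec`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(c("naive", "laparotomy"), seed = 7))
#' head(cohort$measurements)
simulate_cohort <- function(spec, models = domain_models(),
                            effects = group_effects(),
                            anchors = deficit_anchors()) {
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec.")
  missing_models <- setdiff(qor_domains(), models$domain)
  if (length(missing_models)) {
    abort(paste0("Missing domain model(s): ",
                 paste(missing_models, collapse = ", ")))
  }
  missing_eff <- setdiff(spec$groups, effects$group)
  if (length(missing_eff)) {
    abort(paste0("No group effects for: ",
                 paste(missing_eff, collapse = ", ")))
  }
  set.seed(spec$seed)
  units <- domain_units()

  grid <- expand_grid(
    group = spec$groups,
    idx = seq_len(spec$n_per_group),
    domain = models$domain,
    day = spec$days) |>
    mutate(animal_id = sprintf("%s_%02d", .data$group, .data$idx)) |>
    left_join(models, by = "domain") |>
    left_join(effects, by = "group") |>
    mutate(
      deficit = latent_deficit(.data$day,
                               .data$deficit_magnitude * .data$deficit_scale,
                               .data$recovery_rate))

  # Per-animal stable weight (animals differ in size; weight is not iid noise)
  weights <- grid |>
    distinct(.data$animal_id) |>
    mutate(base_weight = rnorm(n(), 375, 25))

  grid <- grid |>
    left_join(weights, by = "animal_id") |>
    mutate(
      center = case_when(
        .data$domain == "weight_g" ~
          .data$base_weight * (1 + 0.008 * .data$day * (1 - .data$deficit)),
        .data$domain %in% names(anchors) ~
          .data$healthy_mean +
            .data$deficit * (unname(anchors[.data$domain]) - .data$healthy_mean),
        .default = .data$healthy_mean * (1 - 0.5 * .data$deficit)))

  n <- nrow(grid)
  z <- rnorm(n)
  # baseline food/water: mean of 3 simulated pre-op days -> SE = sd/sqrt(3)
  avg3 <- grid$day == 0 & grid$domain %in% c("food_g", "water_ml")
  meas <- grid |>
    mutate(
      sd_eff = ifelse(avg3, .data$healthy_sd / sqrt(3), .data$healthy_sd),
      value = ifelse(
        .data$noise == "lognormal",
        .data$center * 10^(z * .data$sd_eff),
        .data$center + z * ifelse(.data$domain == "weight_g", 3,
                                  .data$sd_eff)),
      value = pmax(.data$value, 0),
      value = ifelse(.data$domain == "sucrose_pref_pct",
                     pmin(.data$value, 100), .data$value),
      unit = unname(units[.data$domain]))

  structure(
    list(
      measurements = meas |>
        select("animal_id", "group", "day", "domain", "value", "unit") |>
        arrange(.data$group, .data$animal_id, .data$day, .data$domain),
      truth = meas |>
        select("animal_id", "group", "day", "domain",
               latent_deficit = "deficit", expected_value = "center") |>
        arrange(.data$group, .data$animal_id, .data$day, .data$domain),
      spec = spec),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(unique(x$measurements$animal_id)), " animals, ",
      length(x$spec$days), " days, seed ", x$spec$seed, "\n", sep = "")
  print(head(x$measurements))
  invisible(x)
}
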