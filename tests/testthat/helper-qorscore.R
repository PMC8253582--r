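# Shared fixture builders (all data generated in code).

# A minimal hand-built measurement table: 2 animals, day-0 baselines equal to
# the healthy medians, and day-1 values chosen so the expected %MPE and
# scores can be verified by hand.
make_measurements <- function() {
  units <- domain_units()
  doms <- qor_domains(scored_only = TRUE)
  baselines <- c(food_g = 17.25, transit_min = 72.5, sucrose_pref_pct = 85,
                 vonfrey_g = 1.2, distance_m = 271.2, social_s = 60)
  day1_a <- c(food_g = 6.75, transit_min = 617, sucrose_pref_pct = 69,
              vonfrey_g = 0.28, distance_m = 138.92, social_s = 48)
  day1_b <- baselines  # at baseline: every %MPE 0, every score 3
  dplyr::bind_rows(
    tibble::tibble(animal_id = "a1", group = "laparotomy", day = 0,
                   domain = doms, value = unname(baselines[doms]),
                   unit = unname(units[doms])),
    tibble::tibble(animal_id = "a1", group = "laparotomy", day = 1,
                   domain = doms, value = unname(day1_a[doms]),
                   unit = unname(units[doms])),
    tibble::tibble(animal_id = "n1", group = "naive", day = 0,
                   domain = doms, value = unname(baselines[doms]),
                   unit = unname(units[doms])),
    tibble::tibble(animal_id = "n1", group = "naive", day = 1,
                   domain = doms, value = unname(day1_b[doms]),
                   unit = unname(units[doms])))
}

# Day-1 composites of a freshly simulated cohort (days 0 and 1 only).
sim_day1_composites <- function(seed, groups = qor_groups(),
                                effects = group_effects(), n = 6) {
  co <- simulate_cohort(cohort_spec(groups, n, days = c(0, 1), seed = seed),
                        effects = effects)
  daily_composites(compute_mpe(co$measurements)) |>
    dplyr::filter(day == 1)
}

# Composite total for one animal-day given named per-domain measurements and
# baselines; vector-level route independent of the data-frame pipeline.
composite_from_values <- function(values, baselines,
                                  anchors = deficit_anchors()) {
  doms <- names(anchors)
  mpe <- percent_mpe(values[doms], baselines[doms], anchors[doms],
                     domain = doms)
  sum(domain_score(mpe$mpe_pct))
}
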