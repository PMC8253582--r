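test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec("lobotomy"), "Unknown group")
  expect_error(cohort_spec(n_per_group = 0), "at least 1")
  expect_error(cohort_spec(days = c(0, 2, 1)), "strictly increasing")
  expect_error(cohort_spec(days = c(1, 2, 3)), "day 0")
  expect_error(simulate_cohort(cohort_spec(),
                               models = domain_models()[-1, ]),
               "Missing domain model")
  expect_error(simulate_cohort(cohort_spec(),
                               effects = group_effects()[-1, ]),
               "No group effects")
})

test_that("the same seed reproduces a bit-identical cohort", {
  a <- simulate_cohort(cohort_spec(seed = 9))
  b <- simulate_cohort(cohort_spec(seed = 9))
  c <- simulate_cohort(cohort_spec(seed = 10))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$measurements$value, c$measurements$value))
})

test_that("every animal carries all six scored domains on post-op days", {
  co <- simulate_cohort(cohort_spec(c("naive", "laparotomy"), 4, seed = 2))
  counts <- co$measurements |>
    dplyr::filter(day > 0, domain %in% qor_domains(TRUE)) |>
    dplyr::count(animal_id, day)
  expect_true(all(counts$n == 6))
})

test_that("zero-deficit groups draw from the healthy distributions", {
  co <- simulate_cohort(cohort_spec("naive", 200, days = c(0, 1), seed = 3))
  expect_true(all(co$truth$latent_deficit == 0))
  day1 <- co$measurements |> dplyr::filter(day == 1)
  models <- domain_models()
  for (d in c("food_g", "distance_m", "social_s")) {
    m <- models$healthy_mean[models$domain == d]
    expect_equal(median(day1$value[day1$domain == d]), m,
                 tolerance = 0.05)
  }
})

test_that("full deficit with no recovery pins expectations at the anchors", {
  models <- domain_models() |>
    dplyr::mutate(deficit_magnitude = ifelse(scored, 1, deficit_magnitude))
  effects <- group_effects() |>
    dplyr::mutate(deficit_scale = ifelse(group == "laparotomy", 1,
                                         deficit_scale),
                  recovery_rate = ifelse(group == "laparotomy", 0,
                                         recovery_rate))
  co <- simulate_cohort(cohort_spec("laparotomy", 100, seed = 4),
                        models = models, effects = effects)
  anchors <- deficit_anchors()
  truth <- co$truth |>
    dplyr::filter(day > 0, domain %in% names(anchors))
  expect_equal(truth$expected_value, unname(anchors[truth$domain]))
  # observed medians sit on the anchors up to noise
  day_med <- co$measurements |>
    dplyr::filter(day > 0, domain %in% c("transit_min", "vonfrey_g")) |>
    dplyr::summarise(med = median(value), .by = domain)
  expect_equal(day_med$med[day_med$domain == "transit_min"], 720,
               tolerance = 0.1)
  expect_equal(day_med$med[day_med$domain == "vonfrey_g"], 0.04,
               tolerance = 0.15)
})

test_that("latent deficits recover monotonically at positive rates", {
  d <- latent_deficit(c(0, 1, 2, 3, 6), 0.8, 0.5)
  expect_equal(d[1], 0)
  expect_equal(d[2], 0.8)
  expect_true(all(diff(d[-1]) < 0))
  expect_error(latent_deficit(1, 1.2, 0.5), "\\[0, 1\\]")
  expect_error(latent_deficit(1, 0.5, -1), "non-negative")
})

test_that("laparotomy day-1 food intake matches the published calibration", {
  co <- simulate_cohort(cohort_spec("laparotomy", 600, days = c(0, 1),
                                    seed = 42))
  food1 <- co$measurements |>
    dplyr::filter(domain == "food_g", day == 1)
  # published laparotomy day-1 median 6.75 g; calibration within 20%
  expect_equal(median(food1$value), 6.75, tolerance = 0.2)
})

test_that("simulated composite medians fall in the published day-1 band", {
  co <- simulate_cohort(cohort_spec("laparotomy", 600, days = c(0, 1),
                                    seed = 42))
  comp <- daily_composites(compute_mpe(co$measurements))
  med <- median(comp$total[comp$day == 1])
  expect_gte(med, 5)
  expect_lte(med, 8)
})
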