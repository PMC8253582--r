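test_that("%MPE rescales between baseline (0%) and anchor (100%)", {
  # identity and anchor endpoints, both anchor directions
  expect_equal(percent_mpe(17.25, 17.25, 0)$mpe_pct, 0)
  expect_equal(percent_mpe(0, 17.25, 0)$mpe_pct, 100)
  expect_equal(percent_mpe(720, 72.5, 720)$mpe_pct, 100)
  # hand arithmetic on the published day-1 medians
  expect_equal(percent_mpe(6.75, 17.25, 0)$mpe_pct, 60.8696, tolerance = 1e-4)
  expect_equal(percent_mpe(617, 72.5, 720)$mpe_pct, 84.0927, tolerance = 1e-4)
})

test_that("%MPE clamps to [0, 100] but keeps the raw value", {
  better <- percent_mpe(20, 17.25, 0)     # ate more than baseline
  expect_equal(better$mpe_pct, 0)
  expect_lt(better$raw_mpe_pct, 0)
  beyond <- percent_mpe(900, 72.5, 720)   # worse than the calibrated maximum
  expect_equal(beyond$mpe_pct, 100)
  expect_gt(beyond$raw_mpe_pct, 100)
  # clamping is idempotent
  once <- percent_mpe(900, 72.5, 720)$mpe_pct
  expect_identical(pmin(pmax(once, 0), 100), once)
  expect_identical(domain_score(once), domain_score(pmin(pmax(once, 0), 100)))
})

test_that("degenerate domains (baseline = anchor) are rejected by name", {
  expect_error(percent_mpe(50, 100, 100, domain = "distance_m"),
               "distance_m")
  # distance baseline at the anchor: the precondition, not a silent Inf
  expect_error(percent_mpe(120, 100, 100, domain = "distance_m"),
               "Degenerate")
})

test_that("domain scores bin %MPE into contiguous half-open quartiles", {
  expect_identical(domain_score(c(0, 24.999, 25, 49.999, 50, 74.999, 75, 100)),
                   c(3L, 3L, 2L, 2L, 1L, 1L, 0L, 0L))
  expect_identical(domain_score(60.8696), 1L)  # the food example
  # literal orientation is the mirror image
  expect_identical(domain_score(c(0, 25, 50, 75, 100), "literal"),
                   c(0L, 1L, 2L, 3L, 3L))
  expect_identical(domain_score(0:100) + domain_score(0:100, "literal"),
                   rep(3L, 101))
  expect_error(domain_score(101), "clamped")
  expect_error(domain_score(-2), "clamped")
})

test_that("daily composite sums six domain scores and bounds at 0 and 18", {
  mpe <- compute_mpe(make_measurements())
  comp <- daily_composites(mpe)
  # the all-baseline animal-day scores the maximum
  expect_identical(comp$total[comp$animal_id == "n1"], 18L)
  # hand-derived scores for the published laparotomy day-1 medians:
  # food 60.9->1, transit 84.1->0, sucrose 20->3, vonfrey 79.3->0,
  # distance 77.3->0, social 30->2  => total 6
  a1 <- mpe[mpe$animal_id == "a1", ]
  expect_identical(setNames(a1$score, a1$domain)[qor_domains(TRUE)],
                   c(food_g = 1L, transit_min = 0L, sucrose_pref_pct = 3L,
                     vonfrey_g = 0L, distance_m = 0L, social_s = 2L))
  expect_identical(comp$total[comp$animal_id == "a1"], 6L)
  expect_true(all(comp$total >= 0 & comp$total <= 18))
})

test_that("incomplete animal-days are an error naming the missing domains", {
  mpe <- compute_mpe(make_measurements())
  expect_error(daily_composites(mpe[mpe$domain != "social_s", ]),
               "social_s")
  expect_error(
    daily_composites(mpe[!(mpe$animal_id == "a1" &
                             mpe$domain %in% c("food_g", "vonfrey_g")), ]),
    "a1 day 1.*food_g.*vonfrey_g")
})

test_that("worsening any single domain never raises the composite", {
  set.seed(401)
  anchors <- deficit_anchors()
  doms <- names(anchors)
  base <- c(food_g = 17.25, transit_min = 72.5, sucrose_pref_pct = 85,
            vonfrey_g = 1.2, distance_m = 271.2, social_s = 60)
  for (i in 1:100) {
    f <- runif(6)  # position of each domain between baseline and anchor
    vals <- base + f * (anchors[doms] - base)
    names(vals) <- doms
    t0 <- composite_from_values(vals, base)
    d <- sample(doms, 1)
    worse <- vals
    worse[d] <- worse[d] + runif(1) * (anchors[d] - worse[d])
    expect_lte(composite_from_values(worse, base), t0)
  }
})

test_that("weight gain and sucrose preference follow their definitions", {
  expect_equal(weight_gain_pct(400, 400), 0)
  expect_equal(weight_gain_pct(420, 400), 5)
  expect_equal(weight_gain_pct(384, 400), -4)
  expect_error(weight_gain_pct(0, 400), "positive")
  expect_equal(sucrose_preference_pct(10, 10), 50)
  expect_equal(sucrose_preference_pct(19, 1), 95)
  expect_equal(sucrose_preference_pct(0, 12), 0)
  expect_error(sucrose_preference_pct(0, 0), "zero")
})
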