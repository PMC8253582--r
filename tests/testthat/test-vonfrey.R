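test_that("default filament set is log-spaced over the configured range", {
  fs <- default_filaments()
  expect_equal(min(fs), 0.04)
  expect_equal(max(fs), 15)
  expect_equal(diff(log10(fs)), rep(mean(diff(log10(fs))), 9))
  expect_error(default_filaments(n = 1), "n >= 2")
})

test_that("staircase ascends/descends to a bound and censors there", {
  fs <- default_filaments()
  lo <- run_staircase(function(f) TRUE, fs)   # always responds
  expect_identical(lo$censored, "low")
  expect_equal(min(lo$trials$force_g), min(fs))
  expect_true(all(diff(lo$trials$force_g) <= 0))
  hi <- run_staircase(function(f) FALSE, fs)  # never responds
  expect_identical(hi$censored, "high")
  expect_equal(max(hi$trials$force_g), max(fs))
  expect_true(all(diff(hi$trials$force_g) >= 0))
})

test_that("deterministic cutpoint yields the hand-traced alternating tail", {
  fs <- default_filaments()
  cut <- sqrt(fs[5] * fs[6])
  s <- run_staircase(function(f) f > cut, fs)
  # start at the geometric-mean filament (f6), then alternate f6 X / f5 O;
  # reversal at trial 2 + four post-reversal trials = six trials
  expect_equal(nrow(s$trials), 6)
  expect_equal(s$trials$force_g, rep(c(fs[6], fs[5]), 3))
  expect_equal(s$trials$response, rep(c(TRUE, FALSE), 3))
  expect_identical(s$censored, "none")
  # the trial cap binds when smaller than the natural stopping point
  s4 <- run_staircase(function(f) f > cut, fs, max_trials = 4)
  expect_equal(nrow(s4$trials), 4)
})

test_that("sessions violating the up-down rule are rejected", {
  fs <- default_filaments()
  expect_error(
    vf_session(c(fs[5], fs[7]), c(TRUE, FALSE), fs),  # down-step expected
    "Staircase rule")
  expect_error(vf_session(c(0.5), TRUE, fs), "not in the filament set")
})

test_that("estimator returns bounds for censored sessions, errors on 1 trial", {
  fs <- default_filaments()
  lo <- run_staircase(function(f) TRUE, fs)
  est_lo <- estimate_threshold(lo)
  expect_equal(est_lo$threshold_g, min(fs))
  expect_true(est_lo$censored)
  hi <- run_staircase(function(f) FALSE, fs)
  est_hi <- estimate_threshold(hi)
  expect_equal(est_hi$threshold_g, max(fs))
  expect_true(est_hi$censored)
  one <- vf_session(fs[5], TRUE, fs)
  expect_error(estimate_threshold(one), "Insufficient")
})

test_that("alternating sessions estimate the geometric mean of the two forces", {
  fs <- default_filaments()
  s <- vf_session(rep(c(fs[6], fs[5]), 3), rep(c(TRUE, FALSE), 3), fs)
  expect_equal(estimate_threshold(s)$threshold_g, sqrt(fs[5] * fs[6]),
               tolerance = 1e-5)
})

test_that("shifting a response pattern one filament scales the estimate", {
  fs <- default_filaments()
  ratio <- 10^mean(diff(log10(fs)))
  pat <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  for (i in 3:7) {
    # forces follow the staircase rule from starting filament i
    forces <- numeric(5); idx <- i
    for (t in 1:5) {
      forces[t] <- fs[idx]
      if (t < 5) idx <- idx + if (pat[t]) -1L else 1L
    }
    s1 <- vf_session(forces, pat, fs)
    forces2 <- numeric(5); idx <- i + 1
    for (t in 1:5) {
      forces2[t] <- fs[idx]
      if (t < 5) idx <- idx + if (pat[t]) -1L else 1L
    }
    s2 <- vf_session(forces2, pat, fs)
    expect_equal(estimate_threshold(s2)$threshold_g /
                   estimate_threshold(s1)$threshold_g,
                 ratio, tolerance = 1e-6)
  }
})

test_that("estimates never leave the filament range", {
  set.seed(42)
  fs <- default_filaments()
  for (i in 1:200) {
    thr <- 10^runif(1, log10(0.01), log10(40))  # may sit outside the range
    s <- simulate_vonfrey_responses(thr, fs, slope = 4)
    est <- estimate_threshold(s)
    expect_gte(est$threshold_g, min(fs))
    expect_lte(est$threshold_g, max(fs))
  }
})

test_that("degenerate psychometric slopes give all-or-none sessions", {
  fs <- default_filaments()
  s_all <- simulate_vonfrey_responses(0.01, fs, slope = 1e6, seed = 1)
  expect_true(all(s_all$trials$response))
  expect_identical(s_all$censored, "low")
  s_none <- simulate_vonfrey_responses(100, fs, slope = 1e6, seed = 1)
  expect_false(any(s_none$trials$response))
  expect_identical(s_none$censored, "high")
  expect_error(simulate_vonfrey_responses(1, numeric(0)), "Empty")
  expect_error(simulate_vonfrey_responses(-1, fs), "positive")
})

test_that("up-down estimator tracks a brute-force logistic ML fit", {
  set.seed(7)
  fs <- default_filaments()
  est <- matrix(NA_real_, 500, 2)
  for (i in 1:500) {
    thr <- 10^runif(1, log10(0.1), log10(8))
    s <- simulate_vonfrey_responses(thr, fs, slope = 6)
    est[i, 1] <- estimate_threshold(s)$threshold_g
    # independent oracle: free-slope logistic psychometric, direct ML
    x <- log10(s$trials$force_g)
    r <- as.numeric(s$trials$response)
    nll <- function(p) {
      pr <- plogis(exp(p[2]) * (x - p[1]))
      pr <- pmin(pmax(pr, 1e-9), 1 - 1e-9)
      -sum(r * log(pr) + (1 - r) * log(1 - pr))
    }
    fit <- optim(c(mean(x), log(5)), nll)
    est[i, 2] <- 10^min(max(fit$par[1], log10(min(fs))), log10(max(fs)))
  }
  expect_gt(cor(est[, 1], est[, 2], method = "spearman"), 0.9)
})

test_that("Dixon k factors are antisymmetric and vanish for balanced tails", {
  kt <- dixon_k_table(4)
  k_of <- function(p) kt$k[kt$pattern == p]
  # inverting every response flips the sign of k
  expect_equal(k_of("OOXO"), -k_of("XXOX"), tolerance = 1e-5)
  expect_equal(k_of("OXOX"), -k_of("XOXO"), tolerance = 1e-5)
  # a balanced alternating tail needs no correction
  expect_equal(k_of("OOXX"), 0, tolerance = 1e-5)
  # only patterns containing a reversal are tabulated
  expect_false(any(kt$pattern %in% c("OOOO", "XXXX")))
  expect_equal(nrow(kt), 2^4 - 2)
})

test_that("trial tables round-trip into per-animal-day thresholds", {
  set.seed(5)
  trials <- purrr::map(1:3, function(i) {
    s <- simulate_vonfrey_responses(0.8, slope = 8)
    tibble::tibble(animal_id = paste0("a", i), day = 1,
                   trial_index = seq_len(nrow(s$trials)),
                   force_g = s$trials$force_g,
                   response = s$trials$response)
  }) |> purrr::list_rbind()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(trials, path)
  th <- estimate_thresholds(read_vonfrey_trials(path))
  expect_equal(nrow(th), 3)
  expect_true(all(th$threshold_g >= 0.04 & th$threshold_g <= 15))
  expect_named(th, c("animal_id", "day", "threshold_g", "censored",
                     "n_trials"))
})
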