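# qorscore

Composite quality-of-recovery (QoR) scoring for preclinical rodent
abdominal-surgery studies.

Recovery after laparotomy is multidimensional — a recovering rat eats less,
moves less, avoids a juvenile conspecific, loses sucrose preference,
develops incision-site allodynia and shows delayed intestinal transit.
`qorscore` turns daily measurements of those six behavioral domains into a
single 0–18 composite per animal per day, tracks it across the
post-operative window, and runs the accompanying statistics. It is written
tidyverse-style: data frames in, tibbles out, `ggplot2` plots, and
`tidy()`/`glance()` methods for test objects.

## The score

Each domain measurement is rescaled to percent maximum possible effect
against the animal's own preoperative baseline (0 %) and a fixed
maximum-deficit anchor (100 %) calibrated in a gut ischemia–reperfusion
cohort:

```
%MPE = (test − baseline) / (anchor − baseline) × 100
```

with anchors: food 0 g, intestinal transit 720 min, sucrose preference 5 %,
von Frey threshold 0.04 g, travelled distance 100 m, social exploration
20 s. Clamped %MPE is binned — `[0,25) → 3`, `[25,50) → 2`, `[50,75) → 1`,
`[75,100] → 0` — and the six scores are summed: 18 = little to no
impairment, 0 = gross impairment. Trajectory area-under-the-curve
(trapezoid over days 0–6) summarizes overall recovery; Kruskal–Wallis
(tie-corrected, with exact small-sample permutation p-values) and Dunn
post-hoc tests compare groups.

The package also provides an up-down (Dixon) staircase estimator for the
50 % von Frey withdrawal threshold — the allodynia input to the score — and
a calibrated synthetic-cohort generator, so the entire analysis is testable
and reproducible without animal data. See the methods vignette
(`vignettes/qor-composite-scoring.Rmd`) for the model, the calibration and
every numerical choice.

## Worked example

Simulate a two-arm cohort (6 naive, 6 laparotomy; days 0, 1, 2, 3, 6),
score it, and compare the arms:

```r
library(qorscore)
library(dplyr)

cohort     <- simulate_cohort(cohort_spec(c("naive", "laparotomy"),
                                          n_per_group = 6, seed = 1))
mpe        <- compute_mpe(cohort$measurements)
composites <- daily_composites(mpe)
group_trajectory_summary(build_trajectories(composites))
#> # A tibble: 10 × 6
#>    group        day     n median   q25   q75
#>    <chr>      <dbl> <int>  <dbl> <dbl> <dbl>
#>  1 laparotomy     0     6   18   18    18
#>  2 laparotomy     1     6    7.5  6.25  8.75
#>  3 laparotomy     2     6   13.5 13    14
#>  4 laparotomy     3     6   15   14.2  15.8
#>  5 laparotomy     6     6   17   15.5  17.8
#>  6 naive          0     6   18   18    18
#>  7 naive          1     6   17   16    18
#>  ...
```

Surgery knocks the composite from 18 to a median of 7.5 on day 1, with
recovery by day 6 — naive animals stay at 16–18 throughout. The trajectory
AUC separates the arms:

```r
trajectory_auc(build_trajectories(composites)) |>
  summarise(mean_auc = mean(auc), se = sd(auc) / sqrt(n()), .by = group)
#> # A tibble: 2 × 3
#>   group      mean_auc    se
#> 1 laparotomy     83.7  1.58
#> 2 naive         103.   2.10

kruskal_wallis(filter(composites, day == 1), total, group)
#> Kruskal-Wallis rank sum test (tie-corrected)
#> H = 8.4857, df = 1, p (chi-square) = 0.003579
```

An AUC near 103 score-days is an essentially unimpaired week (a constant
17 over days 0–6 gives exactly 102); the operated arm loses ~19 score-days,
and the day-1 difference is detected at n = 6 per group.

The von Frey staircase estimator, on a simulated session with a true
threshold of 0.6 g:

```r
ses <- simulate_vonfrey_responses(true_threshold_g = 0.6, slope = 8, seed = 11)
estimate_threshold(ses)
#> # A tibble: 1 × 4
#>   threshold_g censored     k n_trials
#> 1       0.317 FALSE    0.144        7
```

(X/O trial sequences, Dixon's k correction computed from the terminal
response pattern; single-session estimates scatter around the truth within
about one filament step — the tests verify the median over 1000 sessions
lands within half a log-step.)

`run_pipeline(measurements, run_config(), outdir)` executes every stage on
a validated long-format CSV and writes the %MPE audit, composites,
trajectories, AUCs, group comparisons and a manifest;
`inst/cli/qor.R` wraps the same functions as a small command line
(`simulate`, `vonfrey`, `score`, `compare`, `run`).

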