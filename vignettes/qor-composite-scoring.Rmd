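---
title: "Composite quality-of-recovery scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite quality-of-recovery scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qorscore)
library(dplyr)
```

## The measurement model

Recovery after abdominal surgery in the rat is multidimensional: a recovering
animal eats less, moves less, interacts less with a juvenile conspecific,
loses its preference for sweet solutions, develops mechanical allodynia at
the incision site, and shows delayed intestinal transit. `qorscore`
implements a composite score that aggregates these six behavioral domains
into a single daily 0–18 quality-of-recovery (QoR) number per animal.

Each domain measurement is first rescaled to *percent maximum possible
effect*:

$$\%MPE = \frac{\text{test} - \text{baseline}}
               {\text{anchor} - \text{baseline}} \times 100$$

where *baseline* is the animal's own preoperative value and *anchor* is a
fixed worst-case ("maximum deficit") value calibrated in a gut
ischemia–reperfusion injury cohort: food 0 g, intestinal transit 720 min,
sucrose preference 5 %, von Frey threshold 0.04 g, travelled distance 100 m,
social exploration 20 s (`deficit_anchors()`). The formula is
direction-agnostic — transit worsens upward, every other domain worsens
downward — because numerator and denominator share the sign of the
deficit direction.

Clamped %MPE is binned into an integer domain score and the six scores are
summed:

| %MPE | score |
|------|-------|
| [0, 25)   | 3 |
| [25, 50)  | 2 |
| [50, 75)  | 1 |
| [75, 100] | 0 |

so 18 means "little to no impairment" and 0 "gross impairment".

### Design choices in the scoring rules

**Bin orientation.** The bin table above awards 3 points for *small*
deficits. The alternative orientation (3 points for 75–100 % MPE) is
arithmetically possible but internally inconsistent: it would make an
uninjured animal score 0 and a maximally injured one 18, the reverse of the
scale's stated meaning, and incompatible with unoperated controls sitting
near 17–18. We therefore use the orientation shown by default and keep the
mirror image available for audit (`domain_score(x, "literal")`); the two
always sum to 3.

**Half-open bins.** Written as integer ranges, quartile bins leave
non-integer values such as 74.5 % unassigned. The implementation uses
contiguous half-open intervals `[0,25), [25,50), [50,75), [75,100]`, which
agree with the integer ranges everywhere both are defined.

**Clamping.** Raw %MPE below 0 (better than baseline) or above 100 (worse
than the ischemia calibration) is clamped so scores stay in 0–3; the
unclamped value is preserved in the audit table (`raw_mpe_pct`). Clamping is
idempotent, so scoring a clamped value again changes nothing.

**Sucrose preference.** The source protocol exempts sucrose preference from
the %MPE transformation yet still specifies a 5 % anchor for it and no
alternative rule. We apply the same %MPE formula with that anchor and flag
the domain as a documented caveat: any other treatment of this domain is
unrecoverable from the protocol text.

**Baselines.** Food and water baselines are the mean of the three
preoperative days (the protocol averages intake); the other domains use the
single preoperative test. In the CSV dialect, preoperative days are recorded
as negative days and collapsed to day 0 on read. Day 0 is therefore *exactly*
the baseline, every day-0 %MPE is 0, and every trajectory starts at
(0, 18).

**Missing domains** invalidate an animal-day (the error lists the absent
domains); the composite is never rescaled from fewer than six domains,
because a 15/15 day and a 15/18 day are not comparable.

Weight change, `100 (w_t - w_0) / w_0`, is reported alongside the composite
but does not enter it.

## Von Frey threshold estimation

The allodynia domain is itself an estimate: the 50 % abdominal-withdrawal
threshold from an up-down (Dixon) staircase of filament presentations.
`run_staircase()` starts at the filament nearest the geometric mean of the
set, steps down after a response and up after no response, and stops once
four trials have been collected after the first response reversal (or at
`max_trials`, or when a bound of the set is occupied on two consecutive
outward-pushing trials — the session is then censored at that bound). The
protocol source does not state its filament set, start force or trial cap,
so all three are configurable; the default set is ten log-spaced forces from
0.04 g (the allodynia anchor) to 15 g.

`estimate_threshold()` implements the Dixon estimator on the log10-force
scale, `threshold = 10^(x_f + k\,\delta)`, with `x_f` the final filament and
`δ` the log-spacing. The correction factor `k` is obtained by the criterion
under which Dixon originally tabulated it — maximum likelihood for a normal
tolerance curve whose spread equals the step size — evaluated exactly on the
session's trials rather than transcribed from the printed table;
`dixon_k_table()` regenerates the pattern-indexed table on demand (balanced
alternating tails give `k = 0`, and inverting every response flips the
sign). Computing `k` instead of transcribing it keeps the estimator defined
for every staircase the rules can produce, including boundary-adjacent
sequences the printed table does not cover. Estimates are clamped to the
filament range and flagged `censored` when clamped.

The test suite validates the estimator two ways: recovery of known
thresholds from simulated logistic-psychometric staircases (median estimate
within half a log-step over 1000 sessions), and rank agreement (Spearman
> 0.9 across 500 sessions) with an independent free-slope logistic ML fit
of the same trials.

## Trajectories, AUC and group comparisons

Per-animal trajectories are the ordered (day, composite) series including
the baseline point (0, 18). `trajectory_auc()` applies the trapezoidal rule
over the observed window (default days 0–6) with no extrapolation; a
constant score *c* over a span *T* gives *cT* score-days, so an unimpaired
animal holding 17 points over days 0–6 yields 102 — the closed form that
anchors the AUC convention. Group summaries report the per-day median with
interquartile range (linear-interpolation sample quantiles, R type 7).

`kruskal_wallis()` computes the tie-corrected H statistic with a chi-square
p-value and, for total n ≤ 10, an exact p-value by complete enumeration of
all assignments of the pooled observations to groups of the observed sizes.
A numerical caution documented here deliberately: with five observations
per group the exact null distribution of H has only thirteen atoms, so the
inclusive exact p-value and the continuous chi-square approximation can
differ by up to ≈ 0.09 in the high-p region (the gap shrinks below 0.05
in the rejection-relevant tail, H ≥ 1.84). This is a property of
small-sample rank statistics, not of the implementation, and is the reason
no blanket equivalence between the two p-values should be expected at these
sample sizes.

`dunn_posthoc()` compares each group with a reference (defaulting to the
unhandled controls) using pooled mean ranks with the tie-corrected variance;
for two groups its z-statistic squares to H exactly. The protocol names both
Dunnett (after RM-ANOVA) and Dunn (after Kruskal–Wallis) without stating
Dunn's multiplicity adjustment; Holm is the default because it dominates
Bonferroni uniformly and requires no independence assumptions, and the
method is configurable. The parametric time-by-treatment repeated-measures
analysis is a thin delegate to `stats::aov()` with the animal as error
stratum (`rm_anova()`): the bespoke content of this package is the score,
the trajectory machinery and the rank tests, not a reimplementation of
ANOVA.

`required_sample_size()` searches ascending n for the smallest group size at
which `stats::power.t.test()` reaches the target power. Under the planning
assumptions of the source study (mean 17, SD 4, 50 % reduction, power 0.8,
two-sided α 0.05) it returns

```{r}
required_sample_size(17, 4, 0.5)
```

which is smaller than the group size of 6 used in that study; the routine
reports its own answer and does not force agreement with any published
planning number.

## The synthetic cohort generator

No animal-level data accompany the protocol, so the generator is the
package's substrate for every end-to-end test. It emulates the study
design: five arms (naive, sham, laparotomy, laparotomy + aspirin,
laparotomy + aspirin + EPA), six animals per arm, observation days
0, 1, 2, 3, 6.

Each domain's latent deficit follows
$d(t) = s_g\, m\, e^{-r_g (t-1)}$ for $t \ge 1$ (0 at baseline): a day-1
trough followed by exponential recovery, the simplest monotone kinetic
consistent with the published trajectory shapes. The expected measurement
moves linearly from the healthy center toward the anchor by $d(t)$;
truncated-normal noise is added, or log-normal noise for the strictly
positive domains (transit, von Frey threshold).

Calibration was fixed once, from the published day-1 group medians:

* healthy centers — food 17.25 g, transit 72.5 min, von Frey 1.2 g,
  distance 271.2 m, sucrose 85 %, social 60 s (the last two are not printed
  and are set to values typical of adult rats in these assays);
* laparotomy day-1 deficit fractions — food 0.609, transit 0.841, von Frey
  0.793, distance 0.773 (each the printed day-1 median mapped through the
  %MPE formula); sucrose 0.20 and social 0.30, matching the reported
  "reduced but not significant" pattern;
* recovery rate 0.5/day for laparotomy, chosen so the noise-free day-2 and
  day-3 composites reproduce the printed medians of 13 and 14.5;
* treatment arms scale the deficit to 0.6 and alter the rate (aspirin
  0.25/day — early improvement, late impairment; aspirin + EPA 0.8/day —
  sustained improvement), sham uses scale 0.2 with rate 1/day;
* spreads derive from the printed interquartile ranges (SD ≈ IQR/1.349),
  except the von Frey domain, whose printed IQR (0.49–2.55 g) folds the
  staircase's quantization into the biological spread; the generator uses
  σ = 0.25 on the log10 scale for the measured threshold.

One published inconsistency is handled explicitly: the day-1 locomotion
medians are printed with the operated group *above* the naive group while
the text describes a reduction; the calibration follows the text (healthy
271.2 m, operated day-1 138.9 m).

The generator intentionally does **not** model cytokine-driven physiology,
intraoperative mortality, per-animal random effects beyond body size, or
day-to-day autocorrelation. Consequently the passing simulation suites
demonstrate that the *pipeline* recovers what the generative model puts in —
calibration of the type-I error, power to detect the surgery effect at
n = 6/group, threshold recovery — not that real cohorts satisfy those
properties.

## Problem sizes and reproducibility

All randomness flows from explicit seeds; the same cohort spec is
bit-identical across runs, and `run_pipeline()` writes a manifest with the
config hash so identical inputs produce byte-identical bundles. The test
suite sizes its simulations as: 1000 staircases for threshold recovery,
1000 zero-effect cohorts for type-I calibration (nominal 5 % ± 2 points),
500 cohorts for day-1 power (≥ 80 %), 500 sessions for the estimator/ML
agreement, and a 600-animal arm for checking the day-1 food calibration
(median within 20 % of 6.75 g) — sizes at which the Monte-Carlo error is
small relative to each tolerance.

## Known limitations

* The sucrose-preference exemption in the source protocol is unresolved;
  the %MPE treatment here is a documented choice, not a reconstruction.
* Whether the original authors clamped out-of-range %MPE is unstated; this
  implementation clamps and records the raw value.
* The published day-1 composite comparison reports P = 0.144 while being
  described as significant; the package takes no side — it simply reports
  the statistics it computes.
* Composites are discrete (19 levels); at n = 6/group their rank tests rely
  on the tie-corrected chi-square approximation, whose small-sample
  discreteness is discussed above.
* The exact permutation test enumerates all label assignments and is
  restricted to total n ≤ 10 by default; beyond that its cost grows
  multinomially.
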