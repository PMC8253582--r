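#' Percent maximum possible effect (%MPE)
#'
#' Rescales a measurement between the animal's own preoperative baseline (0%)
#' and the domain's maximum-deficit anchor (100%):
#' \deqn{\%MPE = \frac{test - baseline}{anchor - baseline} \times 100}
#' The formula is direction-agnostic: it is valid whether the anchor lies
#' below the baseline (food, distance, von Frey, social, sucrose) or above it
#' (intestinal transit). Raw values below 0% (better than baseline) or above
#' 100% (beyond the calibrated maximum deficit) are clamped so that binned
#' domain scores stay within 0-3.
#'
#' @param test Measurement value(s).
#' @param baseline Per-animal preoperative baseline value(s).
#' @param anchor Maximum-deficit anchor value(s); see [deficit_anchors()].
#' @param domain Optional domain label(s), used in error messages.
#' @return A tibble with columns `raw_mpe_pct` (unclamped) and `mpe_pct`
#'   (clamped to `[0, 100]`), one row per input value.
#' @export
#' @examples
#' percent_mpe(6.75, baseline = 17.25, anchor = 0)    # 60.87% food deficit
#' percent_mpe(617, baseline = 72.5, anchor = 720)    # 84.09% transit deficit
percent_mpe <- function(test, baseline, anchor, domain = NULL) {
  n <- max(length(test), length(baseline), length(anchor))
  test <- rep_len(as.numeric(test), n)
  baseline <- rep_len(as.numeric(baseline), n)
  anchor <- rep_len(as.numeric(anchor), n)
  if (any(!is.finite(test)) || any(!is.finite(baseline)) ||
      any(!is.finite(anchor))) {
    abort("percent_mpe() requires finite test, baseline and anchor values.")
  }
  degenerate <- baseline == anchor
  if (any(degenerate)) {
    lab <- if (!is.null(domain)) {
      paste(unique(rep_len(domain, n)[degenerate]), collapse = ", ")
    } else {
      "unspecified domain"
    }
    abort(paste0("Degenerate domain (baseline equals anchor): ", lab,
                 ". %MPE is undefined when the baseline sits on the anchor."))
  }
  raw <- (test - baseline) / (anchor - baseline) * 100
  tibble(raw_mpe_pct = raw, mpe_pct = pmin(pmax(raw, 0), 100))
}

#' Bin a clamped %MPE into a 0-3 domain score
#'
#' Converts clamped %MPE values into integer domain scores over contiguous
#' half-open quartile bins. The default (`orientation = "inverted"`) awards
#' 3 points for little or no deficit:
#' 3 for \code{[0, 25)}, 2 for \code{[25, 50)}, 1 for \code{[50, 75)},
#' 0 for \code{[75, 100]}. Under this orientation an animal at baseline in
#' every domain scores the maximum composite of 18 ("little to no
#' impairment") and an animal at every anchor scores 0 ("gross impairment").
#'
#' `orientation = "literal"` applies the reverse mapping (3 for
#' \code{[75, 100]}, ..., 0 for \code{[0, 25)}) and is retained for audit:
#' it assigns top marks to maximal deficit and is inconsistent with 18 being
#' the unimpaired end of the scale.
#'
#' @param mpe_pct Clamped %MPE value(s) in `[0, 100]`.
#' @param orientation `"inverted"` (default) or `"literal"`.
#' @return Integer vector of scores in `{0, 1, 2, 3}`.
#' @export
#' @examples
#' domain_score(c(0, 24.9, 25, 60.87, 75, 100))
domain_score <- function(mpe_pct, orientation = c("inverted", "literal")) {
  orientation <- match.arg(orientation)
  mpe_pct <- as.numeric(mpe_pct)
  if (any(!is.finite(mpe_pct)) || any(mpe_pct < 0) || any(mpe_pct > 100)) {
    abort("domain_score() expects clamped %MPE values in [0, 100].")
  }
  idx <- findInterval(mpe_pct, c(25, 50, 75))
  as.integer(if (orientation == "inverted") 3L - idx else idx)
}

#' Compute per-domain %MPE and domain scores for a measurement table
#'
#' Takes long-format measurements (one row per animal, day and domain),
#' extracts each animal's day-0 baseline for every scored domain, and returns
#' the %MPE audit table: raw and clamped %MPE plus the binned 0-3 score for
#' every scored post-operative observation.
#'
#' @param measurements Data frame with columns `animal_id`, `group`, `day`,
#'   `domain`, `value` (long format; day 0 holds the baseline).
#' @param anchors Named anchors, see [deficit_anchors()].
#' @param orientation Bin orientation passed to [domain_score()].
#' @return Tibble with one row per animal x post-op day x scored domain:
#'   `animal_id`, `group`, `day`, `domain`, `value`, `baseline`, `anchor`,
#'   `raw_mpe_pct`, `mpe_pct`, `score`.
#' @export
compute_mpe <- function(measurements, anchors = deficit_anchors(),
                        orientation = c("inverted", "literal")) {
  orientation <- match.arg(orientation)
  req <- c("animal_id", "group", "day", "domain", "value")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols)) {
    abort(paste0("Measurements are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  scored <- measurements |>
    filter(.data$domain %in% names(anchors))
  baselines <- scored |>
    filter(.data$day == 0) |>
    select("animal_id", "domain", baseline = "value")
  postop <- scored |>
    filter(.data$day > 0)
  if (nrow(postop) == 0) {
    abort("No post-operative (day > 0) scored measurements found.")
  }
  joined <- postop |>
    left_join(baselines, by = c("animal_id", "domain"))
  if (anyNA(joined$baseline)) {
    bad <- joined |>
      filter(is.na(.data$baseline)) |>
      distinct(.data$animal_id, .data$domain)
    abort(paste0(
      "Missing day-0 baseline for: ",
      paste(paste0(bad$animal_id, "/", bad$domain), collapse = ", ")))
  }
  joined <- joined |>
    mutate(anchor = unname(anchors[.data$domain]))
  mpe <- percent_mpe(joined$value, joined$baseline, joined$anchor,
                     domain = joined$domain)
  joined |>
    mutate(raw_mpe_pct = mpe$raw_mpe_pct,
           mpe_pct = mpe$mpe_pct,
           score = domain_score(mpe$mpe_pct, orientation)) |>
    select("animal_id", "group", "day", "domain", "value", "baseline",
           "anchor", "raw_mpe_pct", "mpe_pct", "score") |>
    arrange(.data$animal_id, .data$day, .data$domain) |>
    as_tibble()
}

#' Daily 0-18 composite recovery score
#'
#' Sums the six domain scores for each animal-day into the daily composite
#' (0 = gross impairment, 18 = little to no impairment). Days with fewer than
#' the six scored domains are an error, never silently rescaled: the
#' composite is only comparable across animal-days when every domain
#' contributes.
#'
#' @param mpe Output of [compute_mpe()] (columns `animal_id`, `group`, `day`,
#'   `domain`, `score`).
#' @return Tibble with one row per animal-day: `animal_id`, `group`, `day`,
#'   one `score_<domain>` column per scored domain, and `total` in `[0, 18]`.
#' @export
daily_composites <- function(mpe) {
  req <- c("animal_id", "group", "day", "domain", "score")
  missing_cols <- setdiff(req, names(mpe))
  if (length(missing_cols)) {
    abort(paste0("Scored table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  scored_domains <- qor_domains(scored_only = TRUE)
  incomplete <- mpe |>
    summarise(missing = list(setdiff(scored_domains, .data$domain)),
              .by = c("animal_id", "day")) |>
    filter(lengths(.data$missing) > 0)
  if (nrow(incomplete)) {
    msg <- incomplete |>
      mutate(txt = paste0(.data$animal_id, " day ", .data$day, " (missing ",
                          map(.data$missing, paste, collapse = ", "), ")")) |>
      pull("txt")
    abort(paste0("Incomplete animal-day(s), cannot form composite: ",
                 paste(msg, collapse = "; ")))
  }
  wide <- mpe |>
    select("animal_id", "group", "day", "domain", "score") |>
    pivot_wider(names_from = "domain", values_from = "score",
                names_prefix = "score_") |>
    mutate(total = rowSums(across(starts_with("score_")))) |>
    arrange(.data$animal_id, .data$day)
  stopifnot(all(wide$total >= 0 & wide$total <= 18))
  wide |> mutate(total = as.integer(.data$total))
}

#' Weight gain as percent change from baseline
#'
#' Reported alongside (but not inside) the composite score.
#'
#' @param weight Post-operative weight(s), g.
#' @param weight_baseline Pre-operative baseline weight(s), g.
#' @return Numeric percent change, `100 * (weight - baseline) / baseline`.
#' @export
#' @examples
#' weight_gain_pct(420, 400)  # +5%
weight_gain_pct <- function(weight, weight_baseline) {
  weight <- as.numeric(weight)
  weight_baseline <- as.numeric(weight_baseline)
  if (any(!is.finite(weight)) || any(!is.finite(weight_baseline)) ||
      any(weight <= 0) || any(weight_baseline <= 0)) {
    abort("Weights must be finite and strictly positive.")
  }
  100 * (weight - weight_baseline) / weight_baseline
}

#' Sucrose preference
#'
#' Volume of sucrose solution drunk as a percentage of total fluid intake in
#' the two-bottle test (anhedonia readout).
#'
#' @param sucrose_ml Sucrose solution intake, mL.
#' @param water_ml Plain water intake, mL.
#' @return Percent preference, `100 * sucrose / (sucrose + water)`.
#' @export
#' @examples
#' sucrose_preference_pct(19, 1)  # 95%
sucrose_preference_pct <- function(sucrose_ml, water_ml) {
  sucrose_ml <- as.numeric(sucrose_ml)
  water_ml <- as.numeric(water_ml)
  if (any(!is.finite(sucrose_ml)) || any(!is.finite(water_ml)) ||
      any(sucrose_ml < 0) || any(water_ml < 0)) {
    abort("Intake volumes must be finite and non-negative.")
  }
  total <- sucrose_ml + water_ml
  if (any(total <= 0)) {
    abort("Undefined preference: total fluid intake is zero.")
  }
  100 * sucrose_ml / total
}
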