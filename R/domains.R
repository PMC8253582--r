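#' Canonical experimental groups
#'
#' The five treatment arms supported by the cohort simulator and the CSV
#' validator: unhandled controls (`naive`), anesthesia-only controls (`sham`),
#' laparotomy, laparotomy with oral aspirin (`laparotomy_asa`), and laparotomy
#' with aspirin plus dietary eicosapentaenoic acid (`laparotomy_asa_epa`).
#'
#' @return Character vector of group labels.
#' @export
qor_groups <- function() {
  c("naive", "sham", "laparotomy", "laparotomy_asa", "laparotomy_asa_epa")
}

#' Behavioral domains
#'
#' Eight behavioral/physiological domains are recorded per animal per day.
#' Six are *scored* (enter the 0-18 composite): daily food intake, intestinal
#' transit time, sucrose preference, von Frey 50% withdrawal threshold,
#' nocturnal travelled distance, and juvenile social exploration. Water intake
#' and body weight are recorded alongside but not scored; weight change from
#' baseline is reported separately (see [weight_gain_pct()]).
#'
#' @param scored_only If `TRUE`, return only the six scored domains.
#' @return Character vector of domain identifiers.
#' @export
qor_domains <- function(scored_only = FALSE) {
  scored <- c("food_g", "transit_min", "sucrose_pref_pct", "vonfrey_g",
              "distance_m", "social_s")
  if (scored_only) scored else c(scored, "water_ml", "weight_g")
}

#' Measurement units by domain
#'
#' @return Named character vector mapping each domain to its unit
#'   (`g`, `mL`, `%`, `m`, `min`, `s`).
#' @export
domain_units <- function() {
  c(food_g = "g", transit_min = "min", sucrose_pref_pct = "%",
    vonfrey_g = "g", distance_m = "m", social_s = "s",
    water_ml = "mL", weight_g = "g")
}

#' Maximum-deficit anchors
#'
#' Fixed worst-case values for the six scored domains, calibrated in a gut
#' ischemia-reperfusion injury cohort: food consumption 0 g, intestinal
#' transit 720 min, sucrose preference 5%, mechanical allodynia (von Frey
#' threshold) 0.04 g, horizontal travelled distance 100 m, juvenile social
#' exploration 20 s. These anchor the 100% end of the %MPE scale; the
#' animal's own preoperative baseline anchors 0%.
#'
#' Individual anchors may be overridden, e.g. `deficit_anchors(transit_min =
#' 600)`; overrides must be finite.
#'
#' @param ... Named scalar overrides for individual domains.
#' @return Named numeric vector of anchors for the six scored domains.
#' @export
#' @examples
#' deficit_anchors()
#' deficit_anchors(distance_m = 50)
deficit_anchors <- function(...) {
  anchors <- c(food_g = 0, transit_min = 720, sucrose_pref_pct = 5,
               vonfrey_g = 0.04, distance_m = 100, social_s = 20)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(anchors))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("Unknown anchor domain(s): ",
                   paste(bad, collapse = ", ")))
    }
    vals <- vapply(dots, function(x) as.numeric(x)[1], numeric(1))
    if (any(!is.finite(vals))) abort("Anchor overrides must be finite.")
    anchors[names(vals)] <- vals
  }
  anchors
}
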