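#' Default von Frey filament set
#'
#' Log-spaced bending forces spanning 0.04 g (the mechanical-allodynia
#' maximum-deficit anchor) to 15 g. The set is configurable throughout the
#' package; equal log spacing makes the up-down estimator's step size
#' `delta_log` well defined.
#'
#' @param n Number of filaments.
#' @param min_g,max_g Range of bending forces (g).
#' @return Strictly increasing numeric vector of forces (g).
#' @export
default_filaments <- function(n = 10, min_g = 0.04, max_g = 15) {
  if (n < 2 || min_g <= 0 || max_g <= min_g) {
    abort("Filament set needs n >= 2 and 0 < min_g < max_g.")
  }
  10^seq(log10(min_g), log10(max_g), length.out = n)
}

#' Construct a von Frey session
#'
#' A session is the ordered list of staircase trials for one test (one animal
#' on one day) together with the filament set in use and a censoring flag.
#' Consecutive trials must obey the up-down rule: after a withdrawal response
#' the next filament is one step down; after no response, one step up, clamped
#' at the ends of the set.
#'
#' @param force_g Ordered filament forces presented (g).
#' @param response Logical: was an abdominal withdrawal response observed?
#' @param filament_set Available forces, strictly increasing.
#' @param censored `"none"`, `"low"` (floor hit) or `"high"` (ceiling hit).
#' @param validate Check the staircase invariant (default `TRUE`).
#' @return Object of class `vf_session`.
#' @export
vf_session <- function(force_g, response, filament_set = default_filaments(),
                       censored = c("none", "low", "high"), validate = TRUE) {
  censored <- match.arg(censored)
  if (length(force_g) != length(response)) {
    abort("force_g and response must have equal length.")
  }
  if (any(diff(filament_set) <= 0)) {
    abort("filament_set must be strictly increasing.")
  }
  response <- as.logical(response)
  idx <- match_force(force_g, filament_set)
  if (validate && length(idx) > 1) {
    k <- length(filament_set)
    expected <- pmin(pmax(idx[-length(idx)] +
                            ifelse(response[-length(response)], -1L, 1L),
                          1L), k)
    if (any(expected != idx[-1])) {
      bad <- which(expected != idx[-1])[1] + 1
      abort(paste0("Staircase rule violated at trial ", bad,
                   ": expected filament ", filament_set[expected[bad - 1]],
                   " g, got ", force_g[bad], " g."))
    }
  }
  structure(
    list(trials = tibble(force_g = filament_set[idx], response = response),
         filament_set = filament_set, censored = censored),
    class = "vf_session")
}

# Map presented forces onto the filament set (tolerant to formatting noise).
match_force <- function(force_g, filament_set) {
  idx <- vapply(force_g, function(f) {
    j <- which.min(abs(log10(filament_set) - log10(f)))
    if (abs(log10(filament_set[j]) - log10(f)) > 1e-6) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) {
    abort(paste0("Force(s) not in the filament set: ",
                 paste(unique(force_g[is.na(idx)]), collapse = ", "), " g."))
  }
  idx
}

#' @export
print.vf_session <- function(x, ...) {
  cat("<vf_session> ", nrow(x$trials), " trials, censored = ", x$censored,
      "\n", sep = "")
  cat(paste0(signif(x$trials$force_g, 3), ifelse(x$trials$response, "X", "O"),
             collapse = " "), "\n")
  invisible(x)
}

#' Run an up-down staircase
#'
#' Presents filaments according to the up-down rule, starting at
#' `start_force_g` (by default the set member nearest the geometric mean of
#' the range): a response moves one filament down, no response one filament
#' up, clamped at the bounds. Testing stops when four trials have been
#' collected after the first response reversal, when `max_trials` is reached,
#' or when a bound has been occupied on two consecutive trials while pushing
#' outward (the session is then censored at that bound).
#'
#' @param responder Function of one argument (force in g) returning `TRUE`
#'   for a withdrawal response. Errors it raises propagate.
#' @param filament_set Strictly increasing available forces (g).
#' @param start_force_g Starting force; must belong to the set.
#' @param max_trials Hard cap on the number of trials (>= 4).
#' @return A [vf_session()].
#' @export
run_staircase <- function(responder, filament_set = default_filaments(),
                          start_force_g = NULL, max_trials = 20) {
  if (length(filament_set) == 0) abort("Empty filament set.")
  if (any(diff(filament_set) <= 0)) {
    abort("filament_set must be strictly increasing.")
  }
  if (max_trials < 4) abort("max_trials must be at least 4.")
  k <- length(filament_set)
  if (is.null(start_force_g)) {
    gm <- sqrt(min(filament_set) * max(filament_set))
    i <- which.min(abs(log10(filament_set) - log10(gm)))
  } else {
    i <- match_force(start_force_g, filament_set)
  }
  idx <- integer(0)
  resp <- logical(0)
  censored <- "none"
  first_reversal <- NA_integer_
  repeat {
    r <- isTRUE(responder(filament_set[i]))
    idx <- c(idx, i)
    resp <- c(resp, r)
    n <- length(idx)
    if (is.na(first_reversal) && n >= 2 && resp[n] != resp[n - 1]) {
      first_reversal <- n
    }
    # censoring: two consecutive trials pinned at a bound, pushing outward
    if (n >= 2) {
      if (idx[n] == 1L && idx[n - 1] == 1L && resp[n] && resp[n - 1]) {
        censored <- "low"
        break
      }
      if (idx[n] == k && idx[n - 1] == k && !resp[n] && !resp[n - 1]) {
        censored <- "high"
        break
      }
    }
    if (!is.na(first_reversal) && n - first_reversal >= 4L) break
    if (n >= max_trials) break
    i <- min(max(i + if (r) -1L else 1L, 1L), k)
  }
  vf_session(filament_set[idx], resp, filament_set, censored = censored,
             validate = FALSE)
}

# Negative log-likelihood of a normal tolerance curve on log10 force with
# fixed spread sigma; response probability rises with force.
vf_nll <- function(mu, x, r, sigma) {
  lp <- pnorm(x, mean = mu, sd = sigma, log.p = TRUE)
  lq <- pnorm(x, mean = mu, sd = sigma, lower.tail = FALSE, log.p = TRUE)
  -sum(r * lp + (1 - r) * lq)
}

# Constrained ML location of the tolerance curve, in log10(g).
vf_ml_mu <- function(x, r, sigma, lo, hi) {
  optimize(vf_nll, interval = c(lo, hi), x = x, r = r, sigma = sigma,
           tol = 1e-7)$minimum
}

#' Estimate the 50% withdrawal threshold from an up-down session
#'
#' Implements the Dixon up-down estimator on the log10 force scale:
#' `threshold = 10^(x_f + k * delta_log)`, where `x_f` is the log10 force of
#' the final trial, `delta_log` is the (mean) log10 spacing of the filament
#' set, and `k` is Dixon's correction factor for the observed response
#' sequence. `k` is computed exactly by the criterion under which Dixon
#' tabulated it — maximum likelihood for a normal tolerance curve whose
#' spread equals the step size — evaluated on the session's actual trials
#' (see [dixon_k_table()] for the pattern-indexed table this induces).
#'
#' Sessions censored at a bound of the filament set return that bound with
#' `censored = TRUE`; estimates never leave the filament range.
#'
#' @param session A [vf_session()].
#' @param delta_log Log10 step size; defaults to the mean log10 spacing of
#'   the session's filament set.
#' @return One-row tibble: `threshold_g`, `censored` (logical), `k`,
#'   `n_trials`.
#' @export
estimate_threshold <- function(session, delta_log = NULL) {
  if (!inherits(session, "vf_session")) {
    abort("estimate_threshold() expects a vf_session.")
  }
  fs <- session$filament_set
  delta <- delta_log %||% mean(diff(log10(fs)))
  if (delta <= 0) abort("delta_log must be positive.")
  tr <- session$trials
  if (session$censored == "low") {
    return(tibble(threshold_g = min(fs), censored = TRUE, k = NA_real_,
                  n_trials = nrow(tr)))
  }
  if (session$censored == "high") {
    return(tibble(threshold_g = max(fs), censored = TRUE, k = NA_real_,
                  n_trials = nrow(tr)))
  }
  if (nrow(tr) < 2) {
    abort("Insufficient data: an uncensored session needs at least 2 trials.")
  }
  x <- log10(tr$force_g)
  r <- as.numeric(tr$response)
  lo <- log10(min(fs))
  hi <- log10(max(fs))
  mu <- vf_ml_mu(x, r, sigma = delta, lo = lo - 4 * delta, hi = hi + 4 * delta)
  k <- (mu - x[length(x)]) / delta
  clamped <- min(max(mu, lo), hi)
  tibble(threshold_g = 10^clamped,
         censored = abs(clamped - mu) > 1e-9,
         k = k, n_trials = nrow(tr))
}

#' Dixon k factors by terminal response pattern
#'
#' For every response pattern of length `pattern_length` that contains a
#' reversal, reconstructs the unique staircase dose sequence it implies (unit
#' steps on an unbounded grid) and computes the correction factor
#' `k = (mu_hat - x_f) / delta` used by [estimate_threshold()]. Patterns are
#' written with `X` = response (step down) and `O` = no response (step up);
#' the final symbol is the last trial.
#'
#' @param pattern_length Number of trials in the terminal sequence.
#' @return Tibble with columns `pattern` and `k`, one row per pattern
#'   containing at least one reversal.
#' @export
#' @examples
#' dixon_k_table(4)
dixon_k_table <- function(pattern_length = 5) {
  if (pattern_length < 2) abort("pattern_length must be at least 2.")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), pattern_length))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- as.logical(grid[i, ])
    if (all(r) || all(!r)) return(NULL)  # no reversal: censored in practice
    x <- cumsum(c(0, ifelse(r[-length(r)], -1, 1)))
    mu <- vf_ml_mu(x, as.numeric(r), sigma = 1,
                   lo = min(x) - 6, hi = max(x) + 6)
    tibble(pattern = paste(ifelse(r, "X", "O"), collapse = ""),
           k = mu - x[length(x)])
  })
  arrange(list_rbind(rows), .data$pattern)
}

#' Simulate staircase responses from a logistic psychometric function
#'
#' Draws trial responses from a logistic psychometric function of log10
#' force centered on a known true threshold, and feeds them through
#' [run_staircase()]; used to validate the estimator by simulation.
#' The response probability at force `f` is
#' `plogis(slope * (log10(f) - log10(true_threshold_g)))`, so steeper slopes
#' approach a deterministic step at the threshold.
#'
#' @param true_threshold_g True 50% threshold (g), > 0.
#' @param filaments Strictly increasing filament forces (g).
#' @param slope Psychometric steepness on the log10 scale.
#' @param seed Optional RNG seed for the session.
#' @param ... Passed on to [run_staircase()] (`start_force_g`, `max_trials`).
#' @return A [vf_session()].
#' @export
simulate_vonfrey_responses <- function(true_threshold_g,
                                       filaments = default_filaments(),
                                       slope = 5, seed = NULL, ...) {
  if (length(filaments) == 0) abort("Empty filament set.")
  if (!is.finite(true_threshold_g) || true_threshold_g <= 0) {
    abort("true_threshold_g must be positive.")
  }
  if (!is.null(seed)) set.seed(seed)
  lt <- log10(true_threshold_g)
  responder <- function(force_g) {
    p <- plogis(slope * (log10(force_g) - lt))
    runif(1) < p
  }
  run_staircase(responder, filament_set = filaments, ...)
}

#' Estimate thresholds for a trial-level table
#'
#' Applies [estimate_threshold()] to each animal-day's ordered trials in a
#' long trial table (the CSV dialect written by the `vonfrey` CLI
#' subcommand).
#'
#' @param trials Data frame with columns `animal_id`, `day`, `trial_index`,
#'   `force_g`, `response`.
#' @param filament_set Available forces.
#' @return Tibble with one row per animal-day: `animal_id`, `day`,
#'   `threshold_g`, `censored`, `n_trials`.
#' @export
estimate_thresholds <- function(trials, filament_set = default_filaments()) {
  req <- c("animal_id", "day", "trial_index", "force_g", "response")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols)) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  trials |>
    arrange(.data$animal_id, .data$day, .data$trial_index) |>
    summarise({
      s <- infer_session(.data$force_g, .data$response, filament_set)
      estimate_threshold(s) |> select(-"k")
    }, .by = c("animal_id", "day"))
}

# Rebuild a session from recorded trials, inferring bound censoring from the
# terminal pattern.
infer_session <- function(force_g, response, filament_set) {
  n <- length(force_g)
  censored <- "none"
  if (n >= 2) {
    at_min <- abs(log10(force_g) - log10(min(filament_set))) < 1e-6
    at_max <- abs(log10(force_g) - log10(max(filament_set))) < 1e-6
    if (at_min[n] && at_min[n - 1] && response[n] && response[n - 1]) {
      censored <- "low"
    } else if (at_max[n] && at_max[n - 1] && !response[n] && !response[n - 1]) {
      censored <- "high"
    }
  }
  vf_session(force_g, response, filament_set, censored = censored)
}
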