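# Rank-based group comparisons: tie-corrected Kruskal-Wallis with exact
# small-sample permutation p-values, and Dunn's post-hoc z-tests against a
# reference group.

kw_statistic <- function(values, groups) {
  n_tot <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rs^2 / ns) - 3 * (n_tot + 1)
  ties <- table(values)
  tie_term <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  if (tie_term <= 0) return(0)  # all observations identical
  h / tie_term
}

# Enumerate all assignments of the pooled values to groups of the observed
# sizes and return the exact permutation distribution of H. Feasible for
# small total n (<= ~12).
kw_exact_p <- function(values, groups, h_obs) {
  sizes <- as.integer(table(groups))
  labs <- names(table(groups))
  n_tot <- length(values)
  stats <- numeric(0)
  assign_rec <- function(remaining, gi, acc) {
    if (gi == length(sizes)) {
      lab <- character(n_tot)
      for (j in seq_along(acc)) lab[acc[[j]]] <- labs[j]
      lab[remaining] <- labs[length(sizes)]
      stats[length(stats) + 1] <<- kw_statistic(values, lab)
      return(invisible(NULL))
    }
    combos <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (cc in combos) {
      assign_rec(setdiff(remaining, cc), gi + 1, c(acc, list(cc)))
    }
  }
  assign_rec(seq_len(n_tot), 1, list())
  mean(stats >= h_obs - 1e-9)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value
#' (`df = k - 1`); for small samples (total n <= 10, or on request) an exact
#' p-value is also computed by full enumeration of all assignments of the
#' pooled observations to groups of the observed sizes. If every observation
#' is identical the test degenerates to H = 0, p = 1.
#'
#' @param data Data frame of observations.
#' @param value,group Columns holding the response and the group label
#'   (tidy-eval).
#' @param exact `TRUE`/`FALSE` to force or suppress the exact permutation
#'   p-value; default (`NULL`) computes it when total n <= 10.
#' @return Object of class `qor_kw` with fields `statistic`, `df`,
#'   `p.value` (chi-square), `p.exact` (or `NA`), `n`, `k`, `method`.
#'   [tidy()] and [glance()] methods return one-row tibbles.
#' @export
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6),
#'                     g = rep(c("a", "b"), each = 3))
#' kruskal_wallis(d, y, g)
kruskal_wallis <- function(data, value, group, exact = NULL) {
  v <- rlang::eval_tidy(enquo(value), data)
  g <- as.character(rlang::eval_tidy(enquo(group), data))
  keep <- complete.cases(v, g)
  v <- v[keep]
  g <- g[keep]
  k <- length(unique(g))
  if (k < 2) abort("Kruskal-Wallis needs at least 2 groups.")
  if (any(table(g) == 0) || length(v) == 0) abort("Empty group(s).")
  h <- kw_statistic(v, g)
  n_tot <- length(v)
  all_equal <- length(unique(v)) == 1
  p_chi <- if (all_equal) 1 else pchisq(h, df = k - 1, lower.tail = FALSE)
  do_exact <- isTRUE(exact) || (is.null(exact) && n_tot <= 10)
  p_ex <- if (do_exact && !all_equal) kw_exact_p(v, g, h)
          else if (do_exact) 1 else NA_real_
  structure(
    list(statistic = h, df = k - 1, p.value = p_chi, p.exact = p_ex,
         n = n_tot, k = k,
         method = "Kruskal-Wallis rank sum test (tie-corrected)"),
    class = "qor_kw")
}

#' @export
print.qor_kw <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("H = %.4f, df = %d, p (chi-square) = %.4g", x$statistic, x$df,
              x$p.value))
  if (!is.na(x$p.exact)) cat(sprintf(", p (exact) = %.4g", x$p.exact))
  cat("\n")
  invisible(x)
}

#' @rdname kruskal_wallis
#' @param x A `qor_kw` object.
#' @param ... Unused.
#' @export
tidy.qor_kw <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         p.exact = x$p.exact, method = x$method)
}

#' @rdname kruskal_wallis
#' @export
glance.qor_kw <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         p.exact = x$p.exact, n = x$n, k = x$k)
}

#' Dunn's post-hoc comparisons against a reference group
#'
#' Pairwise z-statistics of mean ranks (pooled ranking, tie-corrected
#' variance) comparing every group with the reference, with configurable
#' multiplicity adjustment (default Holm):
#' \deqn{z = \frac{\bar R_i - \bar R_{ref}}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12 (N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_{ref}}\right)}}}
#'
#' @inheritParams kruskal_wallis
#' @param reference Label of the reference group (default: `"naive"` when
#'   present, else the first group).
#' @param adjust Adjustment method for [stats::p.adjust()].
#' @return Tibble of class `qor_dunn`, one row per non-reference group:
#'   `group`, `reference`, `mean_rank_diff`, `z`, `p.value`, `p.adjusted`.
#' @export
dunn_posthoc <- function(data, value, group, reference = NULL,
                         adjust = "holm") {
  v <- rlang::eval_tidy(enquo(value), data)
  g <- as.character(rlang::eval_tidy(enquo(group), data))
  keep <- complete.cases(v, g)
  v <- v[keep]
  g <- g[keep]
  labs <- unique(g)
  if (length(labs) < 2) abort("Dunn's test needs at least 2 groups.")
  reference <- reference %||% if ("naive" %in% labs) "naive" else labs[1]
  if (!reference %in% labs) {
    abort(paste0("Reference group not present: ", reference))
  }
  n_tot <- length(v)
  r <- rank(v)
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(v)
  var_pool <- n_tot * (n_tot + 1) / 12 -
    sum(ties^3 - ties) / (12 * (n_tot - 1))
  others <- setdiff(labs, reference)
  z <- (mean_ranks[others] - mean_ranks[reference]) /
    sqrt(var_pool * (1 / ns[others] + 1 / ns[reference]))
  z <- as.numeric(z)  # drop the tapply array shape
  z[!is.finite(z)] <- 0  # all values tied: no evidence of a difference
  p <- 2 * pnorm(-abs(z))
  out <- tibble(group = others, reference = reference,
                mean_rank_diff = as.numeric(mean_ranks[others] -
                                              mean_ranks[reference]),
                z = z, p.value = p,
                p.adjusted = p.adjust(p, method = adjust))
  attr(out, "adjust") <- adjust
  class(out) <- c("qor_dunn", class(out))
  out
}

#' @rdname dunn_posthoc
#' @param x A `qor_dunn` object.
#' @param ... Unused.
#' @export
tidy.qor_dunn <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "qor_dunn")
  as_tibble(out)
}
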