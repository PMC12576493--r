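#' Build a 2x2 paired-outcome table
#'
#' @param n number of pairs.
#' @param b treated-only events (discordant).
#' @param c control-only events (discordant).
#' @param a pairs in which both members had the event.
#' @return object of class `paired_table` with counts `a`, `b`, `c`, `d`
#'   and per-arm marginal event counts.
#' @export
paired_table <- function(n, b, c, a = 0) {
  if (any(c(n, a, b, c) < 0) || a + b + c > n)
    stop("invalid paired counts: need a + b + c <= n and all >= 0",
         call. = FALSE)
  structure(list(n = n, a = a, b = b, c = c, d = n - a - b - c,
                 treated_events = a + b, control_events = a + c),
            class = "paired_table")
}

#' Paired table from per-arm marginal counts
#'
#' When only the marginal event counts of each arm are available (as in a
#' published results table), the discordant difference `b - c` is
#' identified even though `b` and `c` separately are not; with the
#' concordant-event count `a` taken as given (default 0) the table is
#' fully determined. The paired risk difference depends only on the
#' marginals, so it is exact regardless of `a`.
#'
#' @param n number of pairs.
#' @param treated_events,control_events marginal event counts per arm.
#' @param a assumed concordant-event count.
#' @export
paired_table_from_margins <- function(n, treated_events, control_events,
                                      a = 0) {
  paired_table(n, b = treated_events - a, c = control_events - a, a = a)
}

#' Tabulate a binary outcome over matched pairs
#'
#' @param pairs a `matched_pairs` object.
#' @param cohort the cohort holding the outcome.
#' @param outcome name of a 0/1 outcome column.
#' @return a [paired_table()].
#' @export
pair_outcome_table <- function(pairs, cohort, outcome = "death") {
  if (!outcome %in% names(cohort))
    stop(sprintf("unknown outcome column `%s`", outcome), call. = FALSE)
  yt <- cohort[[outcome]][match(pairs$pairs$treated_id, cohort$patient_id)]
  yc <- cohort[[outcome]][match(pairs$pairs$control_id, cohort$patient_id)]
  if (anyNA(yt) || anyNA(yc))
    stop(sprintf("outcome `%s` missing for some paired records", outcome),
         call. = FALSE)
  paired_table(n = length(yt), a = sum(yt == 1 & yc == 1),
               b = sum(yt == 1 & yc == 0), c = sum(yt == 0 & yc == 1))
}

#' Paired risk difference with Wald confidence interval
#'
#' `RD = 100 (b - c) / n` percentage points, identical to the difference
#' of the per-arm marginal rates. The 95% CI uses the paired Wald
#' standard error `sqrt((b + c) - (b - c)^2 / n) / n`.
#'
#' @param pt a [paired_table()].
#' @param conf_level confidence level (default 0.95).
#' @return list with `rd`, `ci` (length 2), `se` and the two-sided Wald
#'   `p` value, all on the percent scale.
#' @export
paired_risk_difference <- function(pt, conf_level = 0.95) {
  stopifnot(inherits(pt, "paired_table"))
  if (pt$n < 1) stop("need at least one pair", call. = FALSE)
  b <- pt$b; c <- pt$c; n <- pt$n
  rd <- 100 * (b - c) / n
  se <- 100 * sqrt(max(0, (b + c) - (b - c)^2 / n)) / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- if (se == 0) { if (rd == 0) 1 else 0 } else 2 * pnorm(-abs(rd / se))
  list(rd = rd, ci = c(rd - z * se, rd + z * se), se = se, p = p)
}

#' Exact McNemar test
#'
#' Two-sided exact binomial test on the discordant pairs:
#' `p = min(1, 2 P(Bin(b + c, 1/2) <= min(b, c)))`. With no discordant
#' pairs the test is uninformative and returns 1 with a warning.
#'
#' @param pt a [paired_table()].
#' @return the exact two-sided p value.
#' @export
mcnemar_exact <- function(pt) {
  stopifnot(inherits(pt, "paired_table"))
  m <- pt$b + pt$c
  if (m == 0) {
    warning("no discordant pairs; McNemar test uninformative", call. = FALSE)
    return(1)
  }
  min(1, 2 * pbinom(min(pt$b, pt$c), m, 0.5))
}

#' Conditional (matched-pairs) odds ratio with exact confidence limits
#'
#' `OR = b / c`, the odds ratio conditional on pair membership. Exact 95%
#' limits come from Clopper-Pearson limits for the discordant proportion
#' `theta = b / (b + c)` mapped through `OR = theta / (1 - theta)`. When
#' `c = 0` the OR and upper limit are infinite; when `b = 0` the OR and
#' lower limit are 0; `b = c = 0` is an error.
#'
#' @param pt a [paired_table()].
#' @param conf_level confidence level (default 0.95).
#' @return list with `or` and `ci`.
#' @export
conditional_odds_ratio <- function(pt, conf_level = 0.95) {
  stopifnot(inherits(pt, "paired_table"))
  b <- pt$b; c <- pt$c; m <- b + c
  if (m < 1) stop("no discordant pairs; conditional OR undefined",
                  call. = FALSE)
  alpha <- 1 - conf_level
  lo_t <- if (b == 0) 0 else qbeta(alpha / 2, b, m - b + 1)
  hi_t <- if (b == m) 1 else qbeta(1 - alpha / 2, b + 1, m - b)
  to_or <- function(theta) if (theta >= 1) Inf else theta / (1 - theta)
  list(or = if (c == 0) Inf else b / c,
       ci = c(to_or(lo_t), to_or(hi_t)))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up false-discovery-rate adjustment; missing values are
#' preserved and excluded from the family size.
#'
#' @param p numeric vector of raw p values in `[0, 1]`.
#' @return adjusted p values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
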