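#' Matched subgroup comparison of a binary outcome
#'
#' For one volume stratum, compares the outcome with versus without TEE in
#' each TEE-score subgroup and pooled over scores: per-arm event counts
#' and rates, the paired risk difference with Wald CI and test, the
#' conditional odds ratio with exact CI and exact McNemar test, and
#' Benjamini-Hochberg adjusted p values. The BH family is the six rows of
#' the stratum (pooled + scores 1-5), adjusted separately for the RD-test
#' and OR-test p values.
#'
#' @param cohort scored cohort (must hold `tee_score` and the outcome).
#' @param pairs `matched_pairs` for this cohort; each pair's subgroup is
#'   its treated member's score (stage-2 matching blocks on the score, so
#'   both members agree).
#' @param outcome 0/1 outcome column name.
#' @param stratum label copied into the output.
#' @param conf_level confidence level.
#' @return data.frame with one row per subgroup (`pooled`, `1`..`5`):
#'   counts, percent rates with SEs, RD (percent) with CI and p, OR with
#'   exact CI and p, BH-adjusted p values, and an `unstable` flag for
#'   empty or discordant-free subgroups.
#' @export
subgroup_analysis <- function(cohort, pairs, outcome = "death",
                              stratum = NA_character_, conf_level = 0.95) {
  if (!"tee_score" %in% names(cohort))
    stop("cohort has no `tee_score` column; score it first", call. = FALSE)
  score_t <- cohort$tee_score[match(pairs$pairs$treated_id,
                                    cohort$patient_id)]
  subgroups <- c("pooled", as.character(1:5))
  rows <- lapply(subgroups, function(sg) {
    keep <- if (sg == "pooled") rep(TRUE, nrow(pairs$pairs))
            else !is.na(score_t) & score_t == as.integer(sg)
    sub <- pairs
    sub$pairs <- pairs$pairs[keep, , drop = FALSE]
    one_subgroup_row(sub, cohort, outcome, sg, stratum, conf_level)
  })
  out <- do.call(rbind, rows)
  out$p_rd_bh <- bh_adjust(out$p_rd)
  out$p_or_bh <- bh_adjust(out$p_or)
  rownames(out) <- NULL
  out
}

one_subgroup_row <- function(pairs, cohort, outcome, sg, stratum,
                             conf_level) {
  base <- data.frame(stratum = stratum, subgroup = sg,
                     n_pairs = nrow(pairs$pairs),
                     events_treated = NA_real_, events_control = NA_real_,
                     rate_treated = NA_real_, rate_control = NA_real_,
                     se_treated = NA_real_, se_control = NA_real_,
                     rd = NA_real_, rd_lo = NA_real_, rd_hi = NA_real_,
                     p_rd = NA_real_, or = NA_real_, or_lo = NA_real_,
                     or_hi = NA_real_, p_or = NA_real_, unstable = TRUE,
                     stringsAsFactors = FALSE)
  if (!nrow(pairs$pairs)) return(base)
  pt <- pair_outcome_table(pairs, cohort, outcome)
  rate <- function(x) 100 * x / pt$n
  base$events_treated <- pt$treated_events
  base$events_control <- pt$control_events
  base$rate_treated <- rate(pt$treated_events)
  base$rate_control <- rate(pt$control_events)
  base$se_treated <- 100 * sqrt(pt$treated_events / pt$n *
                                  (1 - pt$treated_events / pt$n) / pt$n)
  base$se_control <- 100 * sqrt(pt$control_events / pt$n *
                                  (1 - pt$control_events / pt$n) / pt$n)
  rd <- paired_risk_difference(pt, conf_level)
  base$rd <- rd$rd; base$rd_lo <- rd$ci[1]; base$rd_hi <- rd$ci[2]
  base$p_rd <- rd$p
  if (pt$b + pt$c >= 1) {
    or <- conditional_odds_ratio(pt, conf_level)
    base$or <- or$or; base$or_lo <- or$ci[1]; base$or_hi <- or$ci[2]
    base$p_or <- suppressWarnings(mcnemar_exact(pt))
    base$unstable <- FALSE
  }
  base
}
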