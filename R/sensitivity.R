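#' Negative-control outcome analysis
#'
#' Re-runs the matched subgroup comparison on new-onset postoperative
#' atrial fibrillation, an outcome not plausibly affected by
#' intraoperative TEE. Under adequate confounding control the pooled
#' conditional OR interval should cover 1; pooled rows whose interval
#' excludes 1 are flagged as evidence of residual bias.
#'
#' @inheritParams subgroup_analysis
#' @param outcome negative-control outcome column.
#' @return a [subgroup_analysis()] table with an extra logical
#'   `residual_bias_flag` on pooled rows.
#' @export
negative_control_analysis <- function(cohort, pairs, outcome = "neg_control",
                                      stratum = NA_character_,
                                      conf_level = 0.95) {
  if (!outcome %in% names(cohort))
    stop(sprintf("negative-control outcome `%s` absent from cohort", outcome),
         call. = FALSE)
  res <- subgroup_analysis(cohort, pairs, outcome, stratum, conf_level)
  res$residual_bias_flag <- res$subgroup == "pooled" & !is.na(res$or_lo) &
    (res$or_lo > 1 | res$or_hi < 1)
  res
}

#' Supplemental clinical outcome comparisons
#'
#' Applies the mortality machinery unchanged to each supplemental outcome
#' (by default coronary reintervention, postoperative stroke, and chest
#' re-exploration for bleeding).
#'
#' @inheritParams subgroup_analysis
#' @param outcomes character vector of 0/1 outcome columns.
#' @return named list of [subgroup_analysis()] tables, one per outcome.
#' @export
supplemental_outcomes <- function(cohort, pairs,
                                  outcomes = c("reintervention", "stroke",
                                               "chest_reexploration"),
                                  stratum = NA_character_,
                                  conf_level = 0.95) {
  miss <- setdiff(outcomes, names(cohort))
  if (length(miss))
    stop("unknown outcome column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stats::setNames(lapply(outcomes, function(oc)
    subgroup_analysis(cohort, pairs, oc, stratum, conf_level)), outcomes)
}
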