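#' Names of the six effect modifiers used by the CATE model
#'
#' Ejection fraction (%), congestive heart failure, preoperative serum
#' creatinine (mg/dL), >50% left-main coronary stenosis, three or more
#' diseased coronaries, and inotrope use within 48 h of surgery.
#'
#' @export
tee_modifiers <- c("ef", "chf", "creatinine", "left_main_gt50",
                   "vessels_ge3", "inotrope_48h")

#' Default matching covariates
#'
#' The covariate set used for propensity estimation and Mahalanobis
#' distances: demographics, admission status, surgery year, comorbidities,
#' hemodynamics, laboratory values, the six effect modifiers, and the STS
#' predicted risk of mortality (PROM) score. Treatment and all outcomes are
#' deliberately excluded.
#'
#' @export
matching_covariates <- c("age", "sex_male", "race", "admit_source",
                         "operative_status", "surgery_year", "arrhythmia",
                         "chf", "cvd", "prev_cabg", "pa_systolic", "ef",
                         "hemoglobin", "inr", "creatinine", "left_main_gt50",
                         "vessels_ge3", "inotrope_48h", "prom")

outcome_columns <- c("death", "neg_control", "reintervention", "stroke",
                     "chest_reexploration")

#' Configuration for the synthetic CABG cohort generator
#'
#' Encodes the generative assumptions the downstream analysis requires:
#' three hospital-volume strata, a logistic treatment-assignment
#' (propensity) model sharing covariates with the outcome models, a logistic
#' operative-mortality model with treatment-by-modifier interactions (the
#' true CATE structure), a negative-control outcome (new-onset postoperative
#' atrial fibrillation) with a configurable treatment effect that defaults
#' to zero, and sparse completely-at-random missingness.
#'
#' Intercepts of the propensity and outcome models are calibrated
#' numerically so that realized marginal rates match `prevalence`,
#' `baseline_mortality` (the mortality rate had nobody been treated) and
#' `neg_control_rate`.
#'
#' @param n named integer vector: patients per volume stratum
#'   (`low`, `medium`, `high`).
#' @param hospitals named integer vector: hospitals per stratum.
#' @param prevalence target marginal probability of receiving TEE.
#' @param baseline_mortality target untreated operative-mortality rate.
#' @param neg_control_rate target marginal rate of the negative-control
#'   outcome (postoperative atrial fibrillation).
#' @param supplemental_rates named rates for the supplemental outcomes
#'   (coronary reintervention, stroke, chest re-exploration); all have zero
#'   treatment effect by construction.
#' @param propensity_coef named log-odds coefficients of the treatment
#'   model on standardized covariates (confounding strengths).
#' @param outcome_coef named log-odds coefficients of the mortality model
#'   on standardized covariates.
#' @param treatment_effect per-stratum list, each with `main` (log-odds
#'   ratio of TEE at modifier reference levels) and `interaction` (named
#'   log-odds coefficients on the six modifiers). The defaults place the
#'   benefit on left-main stenosis, three-or-more-vessel disease and
#'   inotrope use in the low and medium strata and give the high stratum a
#'   null effect.
#' @param neg_control_effect log-odds treatment effect on the
#'   negative-control outcome (default 0 = no causal effect).
#' @param missingness completely-at-random missingness rate applied to
#'   covariates (never to treatment, outcomes, hospital or vessel count).
#' @param exclusion_rates named rates at which records violating each
#'   data-quality exclusion rule are injected (missing TEE, concomitant
#'   non-CABG procedure, missing hospital, missing vessel count,
#'   emergent-salvage/unknown operative status).
#' @param seed integer seed used by [generate_cohort()] unless overridden.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n = c(low = 10000L, medium = 10000L, high = 10000L),
                          hospitals = c(low = 20L, medium = 20L, high = 15L),
                          prevalence = 0.618,
                          baseline_mortality = 0.025,
                          neg_control_rate = 0.25,
                          supplemental_rates = c(reintervention = 0.01,
                                                 stroke = 0.015,
                                                 chest_reexploration = 0.02),
                          propensity_coef = c(age = 0.05, ef = -0.12,
                                              creatinine = 0.10, chf = 0.20,
                                              inotrope_48h = 0.25,
                                              vessels_ge3 = 0.10,
                                              left_main_gt50 = 0.05,
                                              prom = 0.15, transfer = 0.15,
                                              elective = -0.10),
                          outcome_coef = c(age = 0.45, ef = -0.40,
                                           creatinine = 0.35, chf = 0.30,
                                           inotrope_48h = 0.80,
                                           vessels_ge3 = 0.15,
                                           left_main_gt50 = 0.10,
                                           prom = 0.50),
                          treatment_effect = list(
                            low = list(main = 0,
                                       interaction = c(left_main_gt50 = -0.7,
                                                       vessels_ge3 = -0.5,
                                                       inotrope_48h = -1.0)),
                            medium = list(main = 0,
                                          interaction = c(left_main_gt50 = -0.7,
                                                          vessels_ge3 = -0.5,
                                                          inotrope_48h = -1.0)),
                            high = list(main = 0, interaction = numeric(0))),
                          neg_control_effect = 0,
                          missingness = 5e-4,
                          exclusion_rates = c(missing_tee = 0,
                                              concomitant_procedure = 0,
                                              missing_hospital = 0,
                                              missing_vessels = 0,
                                              salvage_or_unknown_status = 0),
                          seed = 1L) {
  strata <- c("low", "medium", "high")
  n <- n[strata]
  if (anyNA(n) || any(n < 0)) stop_field("n", "needs non-negative counts for low/medium/high")
  hospitals <- hospitals[strata]
  if (anyNA(hospitals) || any(hospitals < 1)) stop_field("hospitals", "needs >= 1 hospital per stratum")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_field("prevalence", "must lie in (0, 1)")
  if (baseline_mortality <= 0 || baseline_mortality >= 1)
    stop_field("baseline_mortality", "must lie in (0, 1)")
  if (neg_control_rate <= 0 || neg_control_rate >= 1)
    stop_field("neg_control_rate", "must lie in (0, 1)")
  if (missingness < 0 || missingness >= 1)
    stop_field("missingness", "must lie in [0, 1)")
  if (any(exclusion_rates < 0) || any(exclusion_rates >= 1))
    stop_field("exclusion_rates", "must lie in [0, 1)")
  for (s in strata) {
    te <- treatment_effect[[s]]
    if (is.null(te) || !is.numeric(te$main))
      stop_field("treatment_effect", sprintf("missing `main` for stratum %s", s))
    extra <- setdiff(names(te$interaction), tee_modifiers)
    if (length(extra))
      stop_field("treatment_effect", sprintf("unknown modifier(s): %s",
                                             paste(extra, collapse = ", ")))
  }
  n <- as.integer(n); names(n) <- strata
  hospitals <- as.integer(hospitals); names(hospitals) <- strata
  structure(list(n = n, hospitals = hospitals,
                 prevalence = prevalence,
                 baseline_mortality = baseline_mortality,
                 neg_control_rate = neg_control_rate,
                 supplemental_rates = supplemental_rates,
                 propensity_coef = propensity_coef,
                 outcome_coef = outcome_coef,
                 treatment_effect = treatment_effect,
                 neg_control_effect = neg_control_effect,
                 missingness = missingness,
                 exclusion_rates = exclusion_rates,
                 seed = as.integer(seed)),
            class = "cohort_config")
}
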