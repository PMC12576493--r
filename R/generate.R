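## Synthetic cohort generator.
##
## Marginal covariate distributions are loosely modelled on a contemporary US
## isolated-CABG population (orders of magnitude only): mean age ~66, ~76%
## male, EF ~52%, creatinine ~1.2 mg/dL, ~77% three-or-more-vessel disease.
## Confounding is induced by sharing standardized covariates between the
## treatment-assignment and outcome linear predictors.

## standardized features shared by the propensity and outcome models
std_features <- function(d) {
  cbind(age = (d$age - 66) / 10,
        ef = (d$ef - 52) / 12,
        creatinine = (log(d$creatinine) - log(1.1)) / 0.45,
        chf = d$chf,
        inotrope_48h = d$inotrope_48h,
        vessels_ge3 = d$vessels_ge3,
        left_main_gt50 = d$left_main_gt50,
        prom = (d$prom - 0.02) / 0.02,
        transfer = as.numeric(d$admit_source == "transfer"),
        elective = as.numeric(d$admit_source == "elective"))
}

lin_pred <- function(feat, coefs) {
  coefs <- coefs[names(coefs) %in% colnames(feat)]
  if (!length(coefs)) return(rep(0, nrow(feat)))
  drop(feat[, names(coefs), drop = FALSE] %*% coefs)
}

## intercept such that mean(plogis(a + lp)) == target
calibrate_intercept <- function(lp, target) {
  uniroot(function(a) mean(plogis(a + lp)) - target,
          lower = -30, upper = 30, tol = 1e-10)$root
}

## per-record treatment effect on the log-odds scale
effect_lp <- function(d, te) {
  delta <- rep(te$main, nrow(d))
  ia <- te$interaction
  if (length(ia)) {
    feat <- std_features(d)
    delta <- delta + lin_pred(feat, ia[names(ia) %in% colnames(feat)])
  }
  delta
}

#' Generate a synthetic isolated-CABG cohort
#'
#' Draws hospitals with annual CABG volumes inside each stratum's range,
#' assigns patients to hospitals, simulates baseline covariates, assigns
#' TEE via a logistic propensity model, and draws operative mortality from
#' a logistic model with stratum-specific treatment-by-modifier
#' interactions. The negative-control outcome shares the mortality model's
#' confounders but has the configured (default zero) treatment effect.
#' The true per-record conditional average treatment effect on mortality is
#' returned in the ground-truth column `true_cate` (a probability
#' difference; negative means TEE lowers mortality risk).
#'
#' @param config a [cohort_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a data.frame, one row per surgery, with identifiers, `treated`,
#'   outcome columns, the six effect modifiers, matching covariates,
#'   `annual_volume`, `volume_stratum` and `true_cate`. The caller's RNG
#'   state is left untouched.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  strata <- c("low", "medium", "high")
  vol_range <- list(low = c(20L, 99L), medium = c(100L, 250L),
                    high = c(251L, 600L))
  pieces <- vector("list", length(strata))
  offset <- 0L
  hosp_offset <- 0L
  for (si in seq_along(strata)) {
    s <- strata[si]
    n <- cfg$n[[s]]
    if (n == 0L) { pieces[[si]] <- NULL; next }
    nh <- cfg$hospitals[[s]]
    vols <- sample(seq(vol_range[[s]][1], vol_range[[s]][2]), nh, replace = TRUE)
    hosp <- sample.int(nh, n, replace = TRUE)
    d <- data.frame(
      patient_id = sprintf("P%07d", offset + seq_len(n)),
      hospital_id = sprintf("H%03d", hosp_offset + hosp),
      annual_volume = vols[hosp],
      volume_stratum = s,
      stringsAsFactors = FALSE)
    offset <- offset + n
    hosp_offset <- hosp_offset + nh

    d$age <- round(pmin(95, pmax(18, rnorm(n, 66, 10))), 1)
    d$sex_male <- rbinom(n, 1, 0.761)
    d$race <- sample(c("white", "black", "asian", "aian", "other"), n,
                     replace = TRUE, prob = c(0.843, 0.075, 0.036, 0.007, 0.041))
    d$admit_source <- sample(c("elective", "emergency", "transfer"), n,
                             replace = TRUE, prob = c(0.477, 0.271, 0.252))
    d$operative_status <- sample(c("elective", "urgent", "emergent"), n,
                                 replace = TRUE, prob = c(0.378, 0.585, 0.037))
    d$surgery_year <- sample(2015:2022, n, replace = TRUE)
    d$arrhythmia <- rbinom(n, 1, 0.147)
    d$chf <- rbinom(n, 1, 0.198)
    d$cvd <- rbinom(n, 1, 0.220)
    d$prev_cabg <- rbinom(n, 1, 0.016)
    d$pa_systolic <- round(pmax(12, rnorm(n, 31, 6.8)), 1)
    d$ef <- round(pmin(80, pmax(10, rnorm(n, 52.3, 12.1))), 1)
    d$hemoglobin <- round(pmax(6, rnorm(n, 13.25, 1.98)), 1)
    d$inr <- round(pmax(0.8, rnorm(n, 1.05, 0.2)), 2)
    d$creatinine <- round(exp(rnorm(n, log(1.1), 0.45)), 2)
    d$left_main_gt50 <- rbinom(n, 1, 0.320)
    d$vessels_ge3 <- rbinom(n, 1, 0.770)
    d$inotrope_48h <- rbinom(n, 1, 0.012)
    ## PROM stored as a fraction in [0, 1]; roughly beta-shaped around 2%
    d$prom <- round(plogis(rnorm(n, qlogis(0.018), 0.8)), 4)

    feat <- std_features(d)

    lp_t <- lin_pred(feat, cfg$propensity_coef)
    a_t <- calibrate_intercept(lp_t, cfg$prevalence)
    d$treated <- rbinom(n, 1, plogis(a_t + lp_t))

    lp_y <- lin_pred(feat, cfg$outcome_coef)
    a_y <- calibrate_intercept(lp_y, cfg$baseline_mortality)
    delta <- effect_lp(d, cfg$treatment_effect[[s]])
    p0 <- plogis(a_y + lp_y)
    p1 <- plogis(a_y + lp_y + delta)
    d$true_cate <- p1 - p0
    d$death <- rbinom(n, 1, ifelse(d$treated == 1, p1, p0))

    ## negative control: same confounders, configurable treatment effect
    lp_nc <- 0.6 * lp_y
    a_nc <- calibrate_intercept(lp_nc, cfg$neg_control_rate)
    d$neg_control <- rbinom(n, 1, plogis(a_nc + lp_nc +
                                           cfg$neg_control_effect * d$treated))

    for (oc in names(cfg$supplemental_rates)) {
      lp_s <- 0.3 * lp_y
      a_s <- calibrate_intercept(lp_s, cfg$supplemental_rates[[oc]])
      d[[oc]] <- rbinom(n, 1, plogis(a_s + lp_s))
    }

    d$concomitant_procedure <- 0L
    pieces[[si]] <- d
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty_cohort())
  rownames(out) <- NULL

  ## injected data-quality defects, each record at most one rule
  er <- cfg$exclusion_rates
  if (sum(er) > 0) {
    u <- runif(nrow(out))
    cum <- cumsum(er)
    rule <- cut(u, breaks = c(0, cum, 1), labels = FALSE)
    rule[rule > length(er)] <- NA
    out$treated[which(rule == 1)] <- NA
    out$concomitant_procedure[which(rule == 2)] <- 1L
    out$hospital_id[which(rule == 3)] <- NA
    out$vessels_ge3[which(rule == 4)] <- NA
    idx5 <- which(rule == 5)
    out$operative_status[idx5] <- sample(c("emergent_salvage", "unknown"),
                                         length(idx5), replace = TRUE)
  }

  ## sparse MCAR missingness on covariates only
  if (cfg$missingness > 0) {
    miss_cols <- setdiff(matching_covariates, "vessels_ge3")
    for (cl in miss_cols) {
      hit <- runif(nrow(out)) < cfg$missingness
      out[[cl]][hit] <- NA
    }
  }
  out
}

empty_cohort <- function() {
  d <- data.frame(patient_id = character(0), hospital_id = character(0),
                  annual_volume = integer(0), volume_stratum = character(0),
                  stringsAsFactors = FALSE)
  for (cl in c("age", "sex_male")) d[[cl]] <- numeric(0)
  d$race <- character(0); d$admit_source <- character(0)
  d$operative_status <- character(0)
  for (cl in c("surgery_year", "arrhythmia", "chf", "cvd", "prev_cabg"))
    d[[cl]] <- numeric(0)
  for (cl in c("pa_systolic", "ef", "hemoglobin", "inr", "creatinine",
               "left_main_gt50", "vessels_ge3", "inotrope_48h", "prom",
               "treated", "true_cate", "death", "neg_control",
               "reintervention", "stroke", "chest_reexploration",
               "concomitant_procedure"))
    d[[cl]] <- numeric(0)
  d
}
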