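#' Configuration of the full two-stage pipeline
#'
#' Defaults mirror the study design: a 25% training / 75% validation
#' split within each volume stratum, quintile TEE scores, a 0.2-SD logit
#' propensity caliper, exact matching on surgery year (plus, in stage 2,
#' the TEE score), near-fine balance on admission source, two-sided tests
#' at alpha = 0.05 with Benjamini-Hochberg correction within each stratum,
#' and the rare-outcome E-value convention.
#'
#' @param cohort a [cohort_config()] (or a list of arguments for one).
#' @param train_fraction stage-1 fraction.
#' @param caliper propensity caliper in SD of the logit score.
#' @param exact exact-match variables for both stages.
#' @param fine_balance near-fine-balance variables.
#' @param max_candidates matching sparsification (see [match_spec()]).
#' @param conf_level confidence level.
#' @param conversion OR-to-RR E-value conversion.
#' @param supplemental supplemental outcome columns.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            train_fraction = 0.25, caliper = 0.2,
                            exact = "surgery_year",
                            fine_balance = "admit_source",
                            max_candidates = 30L, conf_level = 0.95,
                            conversion = "rare",
                            supplemental = c("reintervention", "stroke",
                                             "chest_reexploration"),
                            seed = 20260101L) {
  if (is.list(cohort) && !inherits(cohort, "cohort_config"))
    cohort <- do.call(cohort_config, cohort)
  stopifnot(inherits(cohort, "cohort_config"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_field("train_fraction", "must lie in (0, 1)")
  structure(list(cohort = cohort, train_fraction = train_fraction,
                 caliper = caliper, exact = exact,
                 fine_balance = fine_balance,
                 max_candidates = max_candidates, conf_level = conf_level,
                 conversion = conversion, supplemental = supplemental,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value document mirroring [pipeline_config()] /
#' [cohort_config()] arguments under `cohort:`.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read YAML configs",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort)) {
    ## YAML 1.1 reads a bare `n` key as a boolean; map it back
    names(raw$cohort)[names(raw$cohort) %in% c("FALSE", "no")] <- "n"
    if (!is.null(raw$cohort$n)) raw$cohort$n <- unlist(raw$cohort$n)
    if (!is.null(raw$cohort$hospitals))
      raw$cohort$hospitals <- unlist(raw$cohort$hospitals)
  }
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

log_info <- function(...) message(sprintf(...))

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full two-stage TEE-score pipeline
#'
#' Generate (or accept) a cohort, apply the exclusion rules and single
#' imputation, then per volume stratum: stage 1 matches a random training
#' subset, fits the CATE model and derives the quintile TEE score; stage 2
#' scores the reserved validation subset, matches it exactly within score,
#' and runs the matched subgroup comparisons, E-values, negative-control
#' and supplemental analyses.
#'
#' @param config a [pipeline_config()].
#' @param seed optional master seed overriding `config$seed`.
#' @param cohort optional pre-built cohort (skips generation).
#' @param quiet suppress progress messages.
#' @return a report bundle: baseline and exclusion tables, per-stage
#'   balance reports, CATE models and cutpoints, mortality results with
#'   E-values, negative-control and supplemental tables, matched-pair
#'   objects, and run metadata.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         cohort = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(seed)) seed <- config$seed
  say <- if (quiet) function(...) invisible() else log_info

  t0 <- Sys.time()
  if (is.null(cohort)) {
    cohort <- with_stage("generate",
                         generate_cohort(config$cohort,
                                         derive_seed(seed, "generate")))
    say("generate: %d records", nrow(cohort))
  }
  excl <- with_stage("exclusions", apply_exclusions(cohort))
  cohort <- with_stage("imputation", impute_missing(excl$cohort))
  say("exclusions: %d retained of %d",
      nrow(cohort), sum(excl$report$n))
  baseline <- with_stage("baseline", summarize_baseline(cohort))

  split <- with_stage("split",
                      split_train_test(cohort, config$train_fraction,
                                       derive_seed(seed, "split")))
  spec1 <- match_spec(exact = config$exact,
                      fine_balance = config$fine_balance,
                      caliper = config$caliper,
                      max_candidates = config$max_candidates)

  strata <- intersect(c("low", "medium", "high"),
                      unique(cohort$volume_stratum))
  balance <- list(stage1 = list(), stage2 = list())
  models <- cutpoints <- pairs1_all <- pairs2_all <- list()
  results <- nc <- chars <- list()
  suppl <- stats::setNames(vector("list", length(config$supplemental)),
                           config$supplemental)
  scored_test <- list()

  for (s in strata) {
    train <- split$train[split$train$volume_stratum == s, , drop = FALSE]
    test <- split$test[split$test$volume_stratum == s, , drop = FALSE]

    ## stage 1: match the training subset and derive the score
    train_eq <- equalize_arms(train, derive_seed(seed, paste0("thin1-", s)))
    prop1 <- with_stage(paste0("stage1-propensity-", s),
                        fit_propensity(train_eq))
    pairs1 <- with_stage(paste0("stage1-match-", s),
                         match_pairs(train_eq, prop1, spec1))
    say("stage1 %s: %d train records, %d pairs", s, nrow(train),
        nrow(pairs1$pairs))
    balance$stage1[[s]] <- balance_report(train, pairs1)
    stacked <- stack_matched(pairs1, train)
    model <- with_stage(paste0("stage1-cate-", s),
                        fit_cate_model(stacked, s))
    train_cates <- predict_cate(model, stacked)
    sc <- assign_tee_score(train_cates)
    models[[s]] <- model
    cutpoints[[s]] <- sc$cutpoints
    pairs1_all[[s]] <- pairs1

    ## stage 2: score the reserved subset and validate within score
    test$tee_score <- assign_tee_score(train_cates,
                                       predict_cate(model, test))$score
    test_eq <- equalize_arms(test, derive_seed(seed, paste0("thin2-", s)))
    prop2 <- with_stage(paste0("stage2-propensity-", s),
                        fit_propensity(test_eq))
    spec2 <- match_spec(exact = c(config$exact, "tee_score"),
                        fine_balance = config$fine_balance,
                        caliper = config$caliper,
                        max_candidates = config$max_candidates)
    pairs2 <- with_stage(paste0("stage2-match-", s),
                         match_pairs(test_eq, prop2, spec2))
    say("stage2 %s: %d test records, %d pairs", s, nrow(test),
        nrow(pairs2$pairs))
    balance$stage2[[s]] <- balance_report(test, pairs2)
    pairs2_all[[s]] <- pairs2
    scored_test[[s]] <- test

    res <- with_stage(paste0("stage2-inference-", s),
                      subgroup_analysis(test, pairs2, "death", s,
                                        config$conf_level))
    results[[s]] <- sensitivity_table(res, config$conversion)
    nc[[s]] <- with_stage(paste0("negative-control-", s),
                          negative_control_analysis(test, pairs2,
                                                    stratum = s,
                                                    conf_level = config$conf_level))
    sp <- with_stage(paste0("supplemental-", s),
                     supplemental_outcomes(test, pairs2,
                                           config$supplemental, s,
                                           config$conf_level))
    for (oc in config$supplemental)
      suppl[[oc]] <- rbind(suppl[[oc]], sp[[oc]])
    chars[[s]] <- score_characteristics(test, pairs2, s)
    if (any(res$subgroup != "pooled" & res$n_pairs == 0))
      warning(sprintf("stratum %s has empty TEE-score subgroups", s),
              call. = FALSE)
  }

  meta <- list(seed = seed, config = config_fingerprint(config),
               package_version = as.character(utils::packageVersion("teescore")),
               r_version = as.character(getRversion()),
               elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs")))
  structure(list(baseline = baseline, exclusions = excl$report,
                 balance = balance, models = models, cutpoints = cutpoints,
                 results = do.call(rbind, results),
                 sensitivity = do.call(rbind, lapply(results, function(r)
                   r[c("stratum", "subgroup", "or", "or_lo", "or_hi",
                       "evalue_point", "evalue_ci", "conversion")])),
                 negative_control = do.call(rbind, nc),
                 supplemental = suppl,
                 characteristics = do.call(rbind, chars),
                 pairs = list(stage1 = pairs1_all, stage2 = pairs2_all),
                 scored_test = do.call(rbind, scored_test),
                 metadata = meta),
            class = "report_bundle")
}

## When one arm outnumbers the other, draw a random (seeded) subset of the
## majority arm of the minority arm's size before matching. Optimal matching
## with a large majority-arm excess otherwise drops the hardest-to-match
## records systematically, which skews the matched margins of covariates the
## propensity model says are irrelevant; a random subset keeps selection into
## the matched set independent of the covariates.
equalize_arms <- function(cohort, seed) {
  nt <- sum(cohort$treated == 1); nc <- sum(cohort$treated == 0)
  if (nt == nc) return(cohort)
  maj <- if (nt > nc) 1 else 0
  rows_maj <- which(cohort$treated == maj)
  keep <- with_seed(seed, sample(rows_maj, min(nt, nc)))
  cohort[sort(c(which(cohort$treated != maj), keep)), , drop = FALSE]
}

## flat, order-stable fingerprint of the configuration (enough to re-run)
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$cohort <- unclass(cfg$cohort)
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
}

## Table-3-style characteristics of the matched validation sample:
## per subgroup (pooled + scores) and arm, the modifier profile and the
## death rate
score_characteristics <- function(test, pairs, stratum) {
  stacked <- stack_matched(pairs, test)
  rows <- list()
  for (sg in c("pooled", as.character(1:5))) {
    sub <- if (sg == "pooled") stacked
           else stacked[stacked$tee_score == as.integer(sg), , drop = FALSE]
    for (arm in c(0, 1)) {
      d <- sub[sub$treated == arm, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, subgroup = sg,
        arm = if (arm == 1) "with_tee" else "without_tee",
        n = nrow(d),
        ef_mean = mean(d$ef), ef_lt55_pct = 100 * mean(d$ef < 55),
        chf_pct = 100 * mean(d$chf),
        creatinine_mean = mean(d$creatinine),
        left_main_pct = 100 * mean(d$left_main_gt50),
        vessels_ge3_pct = 100 * mean(d$vessels_ge3),
        inotrope_pct = 100 * mean(d$inotrope_48h),
        prom_mean_pct = 100 * mean(d$prom),
        death_rate_pct = 100 * mean(d$death),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("TEE-score report bundle: %d strata, %d mortality rows, seed %s\n",
              length(x$models), nrow(x$results), x$metadata$seed))
  invisible(x)
}
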