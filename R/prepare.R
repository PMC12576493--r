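#' Apply the cohort data-quality exclusion rules
#'
#' Removes, in order: records with missing TEE status, concomitant
#' non-CABG cardiac procedures, missing hospital identifier, missing
#' diseased-vessel count, and emergent-salvage or unknown operative status.
#' A record violating several rules is counted once, under the first rule
#' that matches.
#'
#' @param cohort a cohort data.frame.
#' @return a list with `cohort` (retained rows) and `report`, a data.frame
#'   of per-rule removal counts whose counts plus `retained` sum to the
#'   input size.
#' @export
apply_exclusions <- function(cohort) {
  need <- c("treated", "concomitant_procedure", "hospital_id", "vessels_ge3",
            "operative_status")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s) required by exclusion rules: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rules <- list(
    missing_tee = is.na(cohort$treated),
    concomitant_procedure = !is.na(cohort$concomitant_procedure) &
      cohort$concomitant_procedure == 1,
    missing_hospital = is.na(cohort$hospital_id),
    missing_vessels = is.na(cohort$vessels_ge3),
    salvage_or_unknown_status = cohort$operative_status %in%
      c("emergent_salvage", "unknown") | is.na(cohort$operative_status))
  assigned <- rep(NA_integer_, nrow(cohort))
  for (k in seq_along(rules)) {
    hit <- rules[[k]] & is.na(assigned)
    assigned[hit] <- k
  }
  report <- data.frame(rule = c(names(rules), "retained"),
                       n = c(tabulate(assigned, nbins = length(rules)),
                             sum(is.na(assigned))),
                       stringsAsFactors = FALSE)
  list(cohort = cohort[is.na(assigned), , drop = FALSE], report = report)
}

#' Single imputation of residual missingness
#'
#' Continuous columns receive the column median of observed values;
#' categorical columns (character, factor, logical, or numeric coded 0/1)
#' receive the mode. Identifier and outcome columns are never touched.
#'
#' @param cohort a cohort data.frame.
#' @param skip columns excluded from imputation (defaults to identifiers,
#'   treatment and outcomes).
#' @return the cohort with no missing values in the imputed columns.
#' @export
impute_missing <- function(cohort,
                           skip = c("patient_id", "hospital_id", "treated",
                                    "true_cate", outcome_columns)) {
  for (cl in setdiff(names(cohort), skip)) {
    x <- cohort[[cl]]
    if (!anyNA(x)) next
    if (all(is.na(x)))
      stop(sprintf("column `%s` is entirely missing; cannot impute", cl),
           call. = FALSE)
    fill <- if (is.numeric(x) && !is_binary_col(x)) median(x, na.rm = TRUE)
            else stat_mode(x)
    x[is.na(x)] <- fill
    cohort[[cl]] <- x
  }
  cohort
}

#' Classify hospitals by annual isolated-CABG volume
#'
#' Low: fewer than 100 cases/year; medium: 100 to 250; high: more than 250.
#'
#' @param annual_volume positive integer vector of annual case counts.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
assign_volume_stratum <- function(annual_volume) {
  if (any(is.na(annual_volume)) || any(annual_volume < 1))
    stop("annual_volume must be a positive case count", call. = FALSE)
  out <- ifelse(annual_volume < 100, "low",
                ifelse(annual_volume <= 250, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Baseline characteristics table
#'
#' Per-group descriptive statistics in the shape of an unadjusted baseline
#' table: mean and SD for continuous covariates, count and percentage for
#' each level of categorical covariates, with an overall column. The SD of
#' a single observation is reported as 0 with a warning.
#'
#' @param cohort a cohort data.frame (non-empty).
#' @param group name of the binary grouping column (default `treated`).
#' @param covariates columns to summarize.
#' @return long-format data.frame: `variable`, `level` (`NA` for
#'   continuous), `group` (`overall` plus one per group value), `n`,
#'   `mean`, `sd`, `count`, `pct`.
#' @export
summarize_baseline <- function(cohort, group = "treated",
                               covariates = intersect(matching_covariates,
                                                      names(cohort))) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  if (!group %in% names(cohort))
    stop(sprintf("unknown grouping column `%s`", group), call. = FALSE)
  groups <- c(list(overall = rep(TRUE, nrow(cohort))),
              lapply(stats::setNames(nm = sort(unique(cohort[[group]]))),
                     function(g) cohort[[group]] == g))
  names(groups) <- c("overall", paste0(group, "=", names(groups)[-1]))
  rows <- list()
  for (v in covariates) {
    x <- cohort[[v]]
    continuous <- is.numeric(x) && !is_binary_col(x)
    for (gn in names(groups)) {
      xs <- x[groups[[gn]]]
      n <- sum(!is.na(xs))
      if (continuous) {
        s <- if (n == 1) { warning(sprintf("single observation for `%s` in %s; SD reported as 0", v, gn),
                                   call. = FALSE); 0 } else sd(xs, na.rm = TRUE)
        rows[[length(rows) + 1L]] <-
          data.frame(variable = v, level = NA_character_, group = gn, n = n,
                     mean = mean(xs, na.rm = TRUE), sd = s,
                     count = NA_real_, pct = NA_real_)
      } else {
        for (lv in sort(unique(x[!is.na(x)]))) {
          cnt <- sum(xs == lv, na.rm = TRUE)
          rows[[length(rows) + 1L]] <-
            data.frame(variable = v, level = as.character(lv), group = gn,
                       n = n, mean = NA_real_, sd = NA_real_,
                       count = cnt, pct = 100 * cnt / n)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
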