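cohort_required_columns <- c("patient_id", "hospital_id", "annual_volume",
                             "volume_stratum", "treated", "death",
                             tee_modifiers)

cohort_numeric_columns <- c("annual_volume", "age", "sex_male",
                            "surgery_year", "arrhythmia", "chf", "cvd",
                            "prev_cabg", "pa_systolic", "ef", "hemoglobin",
                            "inr", "creatinine", "left_main_gt50",
                            "vessels_ge3", "inotrope_48h", "prom", "treated",
                            "true_cate", "concomitant_procedure",
                            outcome_columns)

#' Read a cohort CSV
#'
#' One header row, snake_case column names, UTF-8, binary fields coded
#' 0/1, missing values as empty fields.
#'
#' @param path file path.
#' @return typed cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = "character", check.names = FALSE)
  miss <- setdiff(cohort_required_columns, names(raw))
  if (length(miss))
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cl in intersect(cohort_numeric_columns, names(raw))) {
    x <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(!is.na(raw[[cl]]) & is.na(x))
    if (length(bad))
      stop(sprintf("malformed numeric in column `%s`, row %d", cl, bad[1]),
           call. = FALSE)
    raw[[cl]] <- x
  }
  raw
}

#' Write a cohort CSV
#'
#' @param cohort cohort data.frame.
#' @param path file path; missing values become empty fields.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a CATE model and its score cutpoints to JSON
#'
#' @param model a `cate_model`.
#' @param cutpoints the 4 quintile boundaries.
#' @param path output path.
#' @param seed seed recorded as metadata.
#' @export
write_cate_model <- function(model, cutpoints, path, seed = NA) {
  obj <- list(stratum = model$stratum,
              coefficients = as.list(model$coefficients),
              cutpoints = cutpoints, n_train = model$n, seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized CATE model
#'
#' @param path JSON path written by [write_cate_model()].
#' @return list with a `cate_model` and its `cutpoints`.
#' @export
read_cate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(coefficients = unlist(obj$coefficients),
                          stratum = obj$stratum, n = obj$n_train,
                          iterations = NA_integer_),
                     class = "cate_model")
  list(model = model, cutpoints = obj$cutpoints)
}

## round selected numeric columns into the report's display precision:
## percent rates to 2 decimals, RD to 3, OR to 2
format_results <- function(res) {
  res$rate_treated_fmt <- sprintf("%.2f (%.2f)", res$rate_treated,
                                  res$se_treated)
  res$rate_control_fmt <- sprintf("%.2f (%.2f)", res$rate_control,
                                  res$se_control)
  res$rd_fmt <- sprintf("%.3f (%.3f to %.3f)", res$rd, res$rd_lo, res$rd_hi)
  res$or_fmt <- sprintf("%.2f (%.2f to %.2f)", res$or, res$or_lo, res$or_hi)
  res
}

#' Write every table of a pipeline report bundle
#'
#' Deterministic file set: `baseline.csv`, `exclusions.csv`,
#' `results_mortality.csv`, `sensitivity.csv`, `negative_control.csv`,
#' `supplemental_<outcome>.csv`, `characteristics.csv`,
#' `balance_stage<k>_<stratum>.csv`, `model_<stratum>.json`, and
#' `metadata.json`. Rewriting the same bundle yields byte-identical files.
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @export
write_results <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop(sprintf("output directory `%s` is not writable", outdir),
         call. = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(outdir, name), row.names = FALSE, na = "")
  wr(bundle$baseline, "baseline.csv")
  wr(bundle$exclusions, "exclusions.csv")
  wr(format_results(bundle$results), "results_mortality.csv")
  wr(bundle$sensitivity, "sensitivity.csv")
  wr(format_results(bundle$negative_control), "negative_control.csv")
  for (oc in names(bundle$supplemental))
    wr(format_results(bundle$supplemental[[oc]]),
       sprintf("supplemental_%s.csv", oc))
  wr(bundle$characteristics, "characteristics.csv")
  for (stage in names(bundle$balance))
    for (s in names(bundle$balance[[stage]]))
      wr(bundle$balance[[stage]][[s]],
         sprintf("balance_%s_%s.csv", stage, s))
  for (s in names(bundle$models))
    write_cate_model(bundle$models[[s]], bundle$cutpoints[[s]],
                     file.path(outdir, sprintf("model_%s.json", s)),
                     seed = bundle$metadata$seed)
  jsonlite::write_json(bundle$metadata, file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
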