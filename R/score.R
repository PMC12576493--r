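#' Stratified train/test split
#'
#' Draws a random `fraction` of records within each volume stratum for
#' score derivation (stage 1) and reserves the rest for validation
#' (stage 2). The split is disjoint, exhaustive and reproducible by seed.
#'
#' @param cohort cohort data.frame with a `volume_stratum` column.
#' @param fraction training fraction in (0, 1); default 0.25.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(cohort, fraction = 0.25, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_field("fraction", "must lie in (0, 1)")
  if (!nrow(cohort)) stop("cohort is empty; no stratum to split", call. = FALSE)
  s_all <- if (is.factor(cohort$volume_stratum)) levels(cohort$volume_stratum)
           else unique(cohort$volume_stratum)
  counts <- table(factor(cohort$volume_stratum, levels = s_all))
  if (any(counts == 0))
    stop("empty volume stratum: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  strata <- as.character(s_all)
  train_rows <- with_seed(seed, {
    unlist(lapply(sort(strata), function(s) {
      rows <- which(cohort$volume_stratum == s)
      sample(rows, size = round(fraction * length(rows)))
    }))
  })
  list(train = cohort[sort(train_rows), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(nrow(cohort)), train_rows)), ,
                     drop = FALSE])
}

#' Stack the records of a matched sample
#'
#' Returns the cohort rows belonging to matched treated and control
#' records, with a `pair_id` column (one id per pair).
#'
#' @param pairs a `matched_pairs` object.
#' @param cohort the cohort the pairs refer to.
#' @return data.frame of 2 x (number of pairs) rows.
#' @export
stack_matched <- function(pairs, cohort) {
  it <- match(pairs$pairs$treated_id, cohort$patient_id)
  ic <- match(pairs$pairs$control_id, cohort$patient_id)
  if (anyNA(it) || anyNA(ic))
    stop("pairs reference records absent from the cohort", call. = FALSE)
  out <- cohort[c(it, ic), , drop = FALSE]
  out$pair_id <- rep(seq_along(it), 2L)
  rownames(out) <- NULL
  out
}

#' Fit the CATE logistic model
#'
#' One maximum-likelihood logistic model of operative mortality on
#' treatment, the six effect modifiers, and all treatment-by-modifier
#' interactions, fitted on the stacked matched training sample. The
#' conditional average treatment effect implied by the model is the
#' mortality-probability difference with versus without TEE at the
#' record's modifier values.
#'
#' @param data stacked matched records (see [stack_matched()]) containing
#'   `death`, `treated` and the six modifiers.
#' @param stratum optional stratum label stored as metadata.
#' @return object of class `cate_model` with 14 coefficients (intercept,
#'   treatment, 6 modifier main effects, 6 interactions).
#' @export
fit_cate_model <- function(data, stratum = NA_character_) {
  miss <- setdiff(c("death", "treated", tee_modifiers), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  X <- cate_design(data)
  sep <- separating_covariates(X, data$death)
  if (length(sep))
    stop("perfect separation on: ", paste(sep, collapse = ", "), call. = FALSE)
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, X), data$death, family = binomial(),
            control = list(maxit = 100)))
  if (!fit$converged)
    stop(sprintf("CATE model did not converge after %d iterations", fit$iter),
         call. = FALSE)
  cf <- fit$coefficients
  if (anyNA(cf)) {
    warning("aliased CATE terms (constant or collinear columns) set to zero: ",
            paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    cf[is.na(cf)] <- 0
  }
  if (any(!is.finite(cf)))
    stop("non-finite CATE coefficients; check the design", call. = FALSE)
  structure(list(coefficients = cf, stratum = stratum,
                 n = nrow(data), iterations = fit$iter),
            class = "cate_model")
}

cate_design <- function(data) {
  mm <- cbind(treated = data$treated)
  for (m in tee_modifiers) mm <- cbind(mm, data[[m]])
  colnames(mm) <- c("treated", tee_modifiers)
  inter <- mm[, tee_modifiers, drop = FALSE] * mm[, "treated"]
  colnames(inter) <- paste0("treated:", tee_modifiers)
  cbind(mm, inter)
}

#' @export
print.cate_model <- function(x, ...) {
  cat(sprintf("CATE logistic model (stratum %s, n = %d)\n", x$stratum, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted conditional average treatment effect
#'
#' `CATE(x) = expit(eta(x, TEE)) - expit(eta(x, no TEE))`: the change in
#' operative-mortality probability attributable to TEE for a patient with
#' modifier values `x`. Always in `[-1, 1]`; negative values mean benefit.
#'
#' @param model a [fit_cate_model()] object.
#' @param records data.frame with the six modifier columns.
#' @return numeric vector of probability differences.
#' @export
predict_cate <- function(model, records) {
  stopifnot(inherits(model, "cate_model"))
  miss <- setdiff(tee_modifiers, names(records))
  if (length(miss))
    stop("records lack modifier column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(records[tee_modifiers]))
    stop("missing modifier values; impute before scoring", call. = FALSE)
  d1 <- records; d1$treated <- 1
  d0 <- records; d0$treated <- 0
  eta <- function(d) {
    X <- cbind(1, cate_design(d))
    drop(X %*% model$coefficients)
  }
  plogis(eta(d1)) - plogis(eta(d0))
}

#' Quintile TEE score from training CATEs
#'
#' Cutpoints are the 20/40/60/80 empirical percentiles (linear
#' interpolation) of the training CATE distribution; they are then applied
#' unchanged to any records to be scored. Score 1 holds the lowest
#' (most beneficial) CATEs and 5 the highest; values tied with a cutpoint
#' go to the lower score. If all training CATEs are identical every record
#' receives score 1 and a warning is emitted.
#'
#' @param train_cates numeric CATEs of the training records (>= 5 values).
#' @param cates CATEs of the records to score (defaults to the training
#'   CATEs themselves).
#' @return list with `cutpoints` (4 non-decreasing boundaries) and `score`
#'   (integer 1-5 per scored record).
#' @export
assign_tee_score <- function(train_cates, cates = train_cates) {
  if (length(train_cates) < 5)
    stop("need at least 5 training CATE values to form quintiles",
         call. = FALSE)
  if (anyNA(train_cates) || anyNA(cates))
    stop("CATE values must be non-missing", call. = FALSE)
  cut <- unname(quantile(train_cates, probs = c(0.2, 0.4, 0.6, 0.8),
                         type = 7))
  if (all(train_cates == train_cates[1]))
    warning("all training CATEs identical; every record scored 1",
            call. = FALSE)
  score <- 1L + findInterval(cates, cut, left.open = TRUE)
  list(cutpoints = cut, score = as.integer(score))
}
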