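#' Fit a treatment-assignment (propensity) model
#'
#' Maximum-likelihood logistic regression of treatment on the matching
#' covariates via iteratively reweighted least squares. Categorical
#' covariates are expanded to treatment-coded indicators. Perfect
#' separation is detected and reported with the offending covariate(s);
#' non-convergence raises an error carrying the iteration count.
#'
#' @param cohort data.frame with a 0/1 `treated` column.
#' @param covariates covariate column names (must not include treatment or
#'   outcome columns).
#' @param treatment name of the treatment column.
#' @return object of class `propensity_model`: coefficients, fitted
#'   probabilities, logit-scale scores, and the design-matrix builder.
#' @export
fit_propensity <- function(cohort, covariates = intersect(matching_covariates,
                                                          names(cohort)),
                           treatment = "treated") {
  forbidden <- intersect(covariates, c(treatment, outcome_columns, "true_cate"))
  if (length(forbidden))
    stop("covariates may not include treatment/outcome columns: ",
         paste(forbidden, collapse = ", "), call. = FALSE)
  t <- cohort[[treatment]]
  if (sum(t == 1) < 1 || sum(t == 0) < 1)
    stop("need at least one treated and one control record", call. = FALSE)
  X <- build_design(cohort, covariates)
  sep <- separating_covariates(X, t)
  if (length(sep))
    stop("perfect separation on covariate(s): ", paste(sep, collapse = ", "),
         call. = FALSE)
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, X), t, family = binomial(),
            control = list(maxit = 100)))
  if (!fit$converged)
    stop(sprintf("propensity model did not converge after %d iterations",
                 fit$iter), call. = FALSE)
  p <- fit$fitted.values
  if (any(p < 1e-10) || any(p > 1 - 1e-10))
    stop("fitted probabilities numerically 0 or 1; near-separation in the design",
         call. = FALSE)
  structure(list(coefficients = fit$coefficients,
                 fitted = p, logit = qlogis(p),
                 covariates = covariates, converged = fit$converged,
                 iterations = fit$iter),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("propensity model: %d coefficients, %d records, converged in %d IRLS iterations\n",
              length(x$coefficients), length(x$fitted), x$iterations))
  invisible(x)
}

## numeric design matrix (no intercept); factors as treatment-coded dummies
build_design <- function(cohort, covariates) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop("unknown covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- cohort[covariates]
  na_cols <- names(d)[vapply(d, anyNA, logical(1))]
  if (length(na_cols))
    stop("missing values in covariate(s) ",
         paste(na_cols, collapse = ", "),
         "; run impute_missing() first", call. = FALSE)
  for (cl in names(d)) if (is.character(d[[cl]])) d[[cl]] <- factor(d[[cl]])
  mm <- model.matrix(~ ., data = d)
  mm[, -1, drop = FALSE]
}

## covariates whose treated/control supports do not overlap
separating_covariates <- function(X, t) {
  sep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    x1 <- X[t == 1, j]; x0 <- X[t == 0, j]
    if (var(X[, j]) == 0) next
    sep[j] <- max(x1) < min(x0) || max(x0) < min(x1)
  }
  colnames(X)[sep]
}
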