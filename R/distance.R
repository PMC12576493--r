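#' Mahalanobis distance between covariate vectors
#'
#' `d(x, y) = sqrt((x - y)' S^{-1} (x - y))` with `S` the covariance of
#' the matching covariates, ridge-regularized by `ridge * I` so that
#' collinear synthetic covariates still yield a positive-definite metric.
#'
#' @param x,y numeric covariate vectors of equal length.
#' @param sigma covariance matrix (symmetric).
#' @param ridge diagonal regularization added before inversion.
#' @return non-negative scalar distance; zero iff `x == y`.
#' @export
mahalanobis_distance <- function(x, y, sigma, ridge = 1e-8) {
  stopifnot(length(x) == length(y), nrow(sigma) == length(x))
  R <- mahal_chol(sigma, ridge)
  z <- backsolve(R, x - y, transpose = TRUE)
  sqrt(sum(z^2))
}

## upper Cholesky factor of the regularized covariance
mahal_chol <- function(sigma, ridge = 1e-8) {
  sigma <- (sigma + t(sigma)) / 2 + diag(ridge, nrow(sigma))
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R))
    stop("covariance is singular even after ridge regularization",
         call. = FALSE)
  R
}

## rows of X mapped so that Euclidean distance == Mahalanobis distance
mahal_transform <- function(X, ridge = 1e-8) {
  S <- stats::cov(X)
  R <- mahal_chol(S, ridge)
  t(backsolve(R, t(X), transpose = TRUE))
}

#' Standardized mean difference
#'
#' Continuous: `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`; binary proportions:
#' `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`. Values below 0.10
#' are conventionally regarded as acceptable balance. If the pooled
#' variance is zero the SMD is 0 when the means agree and an error
#' otherwise.
#'
#' @param m1,m2 group means (or proportions for `type = "binary"`).
#' @param s1,s2 group SDs (ignored for binary).
#' @param type `"continuous"` or `"binary"`.
#' @return absolute standardized mean difference.
#' @export
compute_smd <- function(m1, m2, s1 = NULL, s2 = NULL,
                        type = c("continuous", "binary")) {
  type <- match.arg(type)
  pooled <- if (type == "binary") (m1 * (1 - m1) + m2 * (1 - m2)) / 2
            else (s1^2 + s2^2) / 2
  if (pooled <= 0) {
    if (isTRUE(all.equal(m1, m2))) return(0)
    stop("zero pooled variance with unequal means; SMD undefined",
         call. = FALSE)
  }
  abs(m1 - m2) / sqrt(pooled)
}

smd_from_vectors <- function(x1, x0) {
  if (is_binary_col(x1) && is_binary_col(x0))
    compute_smd(mean(x1), mean(x0), type = "binary")
  else
    compute_smd(mean(x1), mean(x0), sd(x1), sd(x0), type = "continuous")
}

#' Covariate balance diagnostics before and after matching
#'
#' @param cohort the cohort the pairs were drawn from.
#' @param pairs a `matched_pairs` object.
#' @param covariates covariates to assess (factors are expanded to level
#'   indicators).
#' @param treatment treatment column name.
#' @return data.frame with `covariate`, `smd_before`, `smd_after`, and
#'   logical flags `acceptable` (SMD < 0.10) and `excellent` (SMD < 0.01).
#' @export
balance_report <- function(cohort, pairs,
                           covariates = intersect(matching_covariates,
                                                  names(cohort)),
                           treatment = "treated") {
  X <- build_design(cohort, covariates)
  t <- cohort[[treatment]]
  ids <- cohort$patient_id
  it <- match(pairs$pairs$treated_id, ids)
  ic <- match(pairs$pairs$control_id, ids)
  smd1 <- smd0 <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    smd0[j] <- smd_from_vectors(X[t == 1, j], X[t == 0, j])
    smd1[j] <- if (length(it)) smd_from_vectors(X[it, j], X[ic, j]) else NA_real_
  }
  data.frame(covariate = colnames(X), smd_before = smd0, smd_after = smd1,
             acceptable = smd1 < 0.10, excellent = smd1 < 0.01,
             stringsAsFactors = FALSE)
}
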