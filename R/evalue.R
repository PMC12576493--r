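#' E-value of a point estimate
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need to have with both treatment and
#' outcome to fully explain away an observed association. With
#' `RR* = max(RR, 1/RR)`, `E = RR* + sqrt(RR* (RR* - 1))`; `E(1) = 1`.
#' Odds ratios are first converted to risk ratios: for a rare outcome
#' (operative mortality here is under 5%) `RR = OR`; the square-root
#' conversion `RR = sqrt(OR)` is available for common outcomes.
#'
#' @param est positive effect estimate.
#' @param scale `"rr"` if `est` is a risk ratio, `"or"` if an odds ratio.
#' @param conversion OR-to-RR conversion (`"rare"` identity or `"sqrt"`);
#'   ignored for `scale = "rr"`.
#' @return E-value (>= 1).
#' @export
evalue_point <- function(est, scale = c("or", "rr"),
                         conversion = c("rare", "sqrt")) {
  scale <- match.arg(scale)
  conversion <- match.arg(conversion)
  if (!is.finite(est) || est <= 0)
    stop("effect estimate must be a positive number", call. = FALSE)
  rr <- if (scale == "or" && conversion == "sqrt") sqrt(est) else est
  rr_star <- max(rr, 1 / rr)
  rr_star + sqrt(rr_star * (rr_star - 1))
}

#' E-value of a confidence interval
#'
#' If the interval contains the null (1) the CI E-value is 1: no
#' unmeasured confounding is needed to render the association compatible
#' with the null. Otherwise the E-value of the limit closest to 1 is
#' returned.
#'
#' @param ci numeric length-2 interval `(lower, upper)`, `0 < lower <=
#'   upper`.
#' @inheritParams evalue_point
#' @export
evalue_ci <- function(ci, scale = c("or", "rr"),
                      conversion = c("rare", "sqrt")) {
  if (length(ci) != 2 || anyNA(ci) || ci[1] <= 0 || ci[1] > ci[2])
    stop("ci must be (lower, upper) with 0 < lower <= upper", call. = FALSE)
  if (ci[1] <= 1 && ci[2] >= 1) return(1)
  limit <- if (ci[1] > 1) ci[1] else ci[2]
  evalue_point(limit, scale, conversion)
}

#' E-value sensitivity table for a subgroup analysis
#'
#' Appends the point and CI E-values to each subgroup's conditional odds
#' ratio. The headline E-value of a subgroup is the CI-based one: any
#' subgroup whose OR interval crosses 1 reports exactly 1.00.
#'
#' @param results a [subgroup_analysis()] table.
#' @param conversion OR-to-RR conversion used.
#' @return the table with `evalue_point`, `evalue_ci` and `conversion`
#'   columns.
#' @export
sensitivity_table <- function(results, conversion = c("rare", "sqrt")) {
  conversion <- match.arg(conversion)
  ev_pt <- ev_ci <- rep(NA_real_, nrow(results))
  for (i in seq_len(nrow(results))) {
    or <- results$or[i]
    if (is.na(or) || !is.finite(or) || or <= 0) next
    ev_pt[i] <- evalue_point(or, "or", conversion)
    lo <- results$or_lo[i]; hi <- results$or_hi[i]
    if (is.na(lo) || is.na(hi)) next
    ev_ci[i] <- if (lo <= 1 && hi >= 1) 1
                else if (hi < 1) evalue_point(hi, "or", conversion)
                else evalue_point(lo, "or", conversion)
  }
  results$evalue_point <- ev_pt
  results$evalue_ci <- ev_ci
  results$conversion <- conversion
  results
}
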