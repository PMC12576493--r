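#' @useDynLib teescore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats glm glm.fit binomial coef fitted median model.matrix
#'   plogis qlogis pbinom pnorm qnorm qbeta quantile rbinom rnorm runif sd
#'   uniroot var
#' @importFrom utils read.csv write.csv
NULL

expit <- function(x) plogis(x)

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Stage-specific seeds derived from one master seed by hashing the stage
## label; kept inside 32-bit range.
derive_seed <- function(seed, stage) {
  k <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483629)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

## statistical mode; ties broken by first-observed order
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

is_binary_col <- function(x) {
  is.numeric(x) && all(x[!is.na(x)] %in% c(0, 1))
}
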