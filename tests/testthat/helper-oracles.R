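## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the logistic oracle is a hand-rolled
## Newton-Raphson, the matching oracle is exhaustive enumeration, and the
## multiplicity oracle is the textbook step-up definition.

## Newton-Raphson maximum-likelihood logistic regression (with intercept).
nr_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- crossprod(X, y - p)
    H <- crossprod(X * W, X)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = drop(beta), vcov = solve(H))
}

## Exhaustive enumeration of 1:1 matchings under the lexicographic
## (pair count, fine-balance discrepancy, total distance) objective.
## Fine-balance targets are the category counts among all treated.
enum_best_matching <- function(adm, dist, tcat, ccat, ncat) {
  nT <- nrow(adm); nC <- ncol(adm)
  target <- tabulate(tcat, nbins = ncat)
  best <- NULL
  rec <- function(i, used, rows, cols) {
    if (i > nT) {
      k <- length(rows)
      mc <- if (k) tabulate(ccat[cols], nbins = ncat) else integer(ncat)
      disc <- sum(abs(target - mc))
      dd <- if (k) sum(dist[cbind(rows, cols)]) else 0
      obj <- c(k, disc, dd)
      if (is.null(best) || obj[1] > best[1] ||
          (obj[1] == best[1] && (obj[2] < best[2] ||
            (obj[2] == best[2] && obj[3] < best[3] - 1e-9))))
        best <<- obj
      return()
    }
    rec(i + 1, used, rows, cols)
    for (j in which(adm[i, ] & !used)) {
      used[j] <- TRUE
      rec(i + 1, used, c(rows, i), c(cols, j))
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, nC), integer(0), integer(0))
  best
}

## Textbook Benjamini-Hochberg step-up adjustment.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    v <- min(1, m * p[ord[i]] / i, prev)
    adj[ord[i]] <- v
    prev <- v
  }
  adj
}

## Exact two-sided McNemar p by explicit binomial enumeration.
mcnemar_brute <- function(b, c) {
  m <- b + c
  if (m == 0) return(1)
  k <- min(b, c)
  tail <- sum(choose(m, 0:k) * 0.5^m)
  min(1, 2 * tail)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

## A hand-built propensity model object with prescribed logit scores,
## for matcher tests that need full control of admissibility.
fake_propensity <- function(logit, covariates) {
  structure(list(coefficients = 0, fitted = plogis(logit), logit = logit,
                 covariates = covariates, converged = TRUE, iterations = 1L),
            class = "propensity_model")
}

## Small random matching instance (cohort + fake propensity scores).
random_match_instance <- function(nT, nC, ncat = 2, seed = 1) {
  set.seed(seed)
  n <- nT + nC
  co <- data.frame(patient_id = sprintf("r%02d", seq_len(n)),
                   treated = rep(c(1, 0), c(nT, nC)),
                   x1 = rnorm(n), x2 = rnorm(n),
                   cat = sample(letters[seq_len(ncat)], n, replace = TRUE),
                   volume_stratum = "low", stringsAsFactors = FALSE)
  list(cohort = co,
       prop = fake_propensity(rnorm(n, 0, 0.5), c("x1", "x2")))
}

## Reconstruct admissibility/distance matrices the way match_pairs defines
## them, for comparison against the enumeration oracle.
instance_matrices <- function(inst, caliper) {
  co <- inst$cohort
  nT <- sum(co$treated == 1); nC <- sum(co$treated == 0)
  X <- cbind(x1 = co$x1, x2 = co$x2)
  S <- stats::cov(X) + diag(1e-8, 2)
  R <- chol(S)
  Z <- t(backsolve(R, t(X), transpose = TRUE))
  lg <- inst$prop$logit
  cal <- caliper * stats::sd(lg)
  adm <- abs(outer(lg[seq_len(nT)], lg[nT + seq_len(nC)], "-")) <= cal
  D <- as.matrix(stats::dist(Z))[seq_len(nT), nT + seq_len(nC), drop = FALSE]
  allcat <- factor(inst$cohort$cat)
  list(adm = adm, dist = D,
       tcat = as.integer(allcat)[seq_len(nT)],
       ccat = as.integer(allcat)[nT + seq_len(nC)],
       ncat = nlevels(allcat))
}

## Small deterministic cohort used by data-preparation tests.
toy_cohort <- function(n = 10, seed = 99) {
  cfg <- cohort_config(n = c(low = n, medium = 0L, high = 0L), seed = seed)
  generate_cohort(cfg)
}
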