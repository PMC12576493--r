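#' Specification of a 1:1 matching problem
#'
#' @param exact covariates on which treated and control must agree exactly
#'   (block matching); default none.
#' @param fine_balance covariates whose category counts are balanced
#'   between the treated and matched-control groups (near-fine balance);
#'   default none.
#' @param caliper maximum within-pair difference in logit propensity, in
#'   multiples of the SD of the logit propensity score.
#' @param mahal_covariates covariates entering the Mahalanobis distance;
#'   defaults to the propensity-model covariates.
#' @param scale distances are multiplied by `scale` and rounded to integer
#'   costs for the network-flow solver (1e4 keeps four decimal places).
#' @param max_candidates sparsification: each treated record is connected
#'   to at most this many caliper-admissible controls, nearest first on the
#'   logit propensity scale. `Inf` disables sparsification (used for exact
#'   optimality on small problems; larger problems are solved on the
#'   sparsified network).
#' @param ridge ridge regularization for the pooled covariance.
#' @return object of class `match_spec`.
#' @export
match_spec <- function(exact = character(0), fine_balance = character(0),
                       caliper = 0.2, mahal_covariates = NULL,
                       scale = 1e4, max_candidates = 30L, ridge = 1e-8) {
  if (!is.numeric(caliper) || caliper <= 0)
    stop_field("caliper", "must be > 0")
  forbidden <- intersect(c(exact, fine_balance),
                         c("treated", outcome_columns, "true_cate"))
  if (length(forbidden))
    stop("matching variables may not include treatment/outcome columns: ",
         paste(forbidden, collapse = ", "), call. = FALSE)
  structure(list(exact = exact, fine_balance = fine_balance,
                 caliper = caliper, mahal_covariates = mahal_covariates,
                 scale = scale, max_candidates = max_candidates,
                 ridge = ridge),
            class = "match_spec")
}

#' Optimal 1:1 pair matching by minimum-cost network flow
#'
#' Within each exact-match block, admissible edges connect treated and
#' control records whose logit propensity scores differ by at most the
#' caliper. The solver maximizes the number of pairs first; among
#' maximum-cardinality matchings it minimizes the total absolute
#' discrepancy between the treated and matched-control category counts of
#' the fine-balance variables (targets taken from all treated in the
#' block); and among those it minimizes the total Mahalanobis distance.
#' The lexicographic priorities are encoded as integer arc costs (distance
#' costs are `round(scale * d)`; each unit of fine-balance overflow costs
#' more than the largest possible total distance), and the problem is
#' solved as an integer minimum-cost flow.
#'
#' @param cohort data.frame with unique `patient_id` and a 0/1 `treated`
#'   column; rows must correspond to the records `prop` was fitted on.
#' @param prop a [fit_propensity()] model for `cohort`.
#' @param spec a [match_spec()].
#' @return object of class `matched_pairs`: `pairs` (data.frame
#'   `treated_id`, `control_id`, `distance`), `n_unmatched_treated`,
#'   `objective` (pairs, fine-balance discrepancy, total distance), and
#'   the `spec` used. With no admissible edges an empty matching is
#'   returned with a warning.
#' @export
match_pairs <- function(cohort, prop, spec = match_spec()) {
  stopifnot(inherits(prop, "propensity_model"), inherits(spec, "match_spec"))
  if (anyDuplicated(cohort$patient_id))
    stop("patient_id must be unique", call. = FALSE)
  if (length(prop$logit) != nrow(cohort))
    stop("propensity model was not fitted on this cohort", call. = FALSE)
  mahal_cov <- spec$mahal_covariates
  if (is.null(mahal_cov)) mahal_cov <- prop$covariates
  X <- build_design(cohort, mahal_cov)
  Z <- mahal_transform(X, spec$ridge)
  logit <- prop$logit
  cal <- spec$caliper * sd(logit)
  if (!is.finite(cal) || cal == 0) cal <- spec$caliper  # degenerate: constant score

  blocks <- if (length(spec$exact))
    interaction(cohort[spec$exact], drop = TRUE, lex.order = TRUE)
  else factor(rep("all", nrow(cohort)))

  all_pairs <- list()
  discrepancy <- 0
  for (b in levels(blocks)) {
    idx <- which(blocks == b)
    res <- match_block(idx, cohort, Z, logit, cal, spec)
    all_pairs[[b]] <- res$pairs
    discrepancy <- discrepancy + res$discrepancy
  }
  pairs <- do.call(rbind, all_pairs)
  if (is.null(pairs) || !nrow(pairs)) {
    warning("no admissible treated-control edges; empty matching returned",
            call. = FALSE)
    pairs <- data.frame(treated_id = character(0), control_id = character(0),
                        distance = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 n_unmatched_treated = sum(cohort$treated == 1) - nrow(pairs),
                 objective = c(pairs = nrow(pairs),
                               fine_balance = discrepancy,
                               distance = sum(pairs$distance)),
                 spec = spec),
            class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("matched pairs: %d pairs, %d unmatched treated, fine-balance discrepancy %g, total distance %.4f\n",
              nrow(x$pairs), x$n_unmatched_treated,
              x$objective[["fine_balance"]], x$objective[["distance"]]))
  invisible(x)
}

## one exact-match block; ids processed in patient_id order for determinism
match_block <- function(idx, cohort, Z, logit, cal, spec) {
  ord <- idx[order(cohort$patient_id[idx])]
  t_idx <- ord[cohort$treated[ord] == 1]
  c_idx <- ord[cohort$treated[ord] == 0]
  nT <- length(t_idx); nC <- length(c_idx)
  empty <- list(pairs = NULL, discrepancy = fb_discrepancy_empty(cohort, t_idx, spec))
  if (nT == 0 || nC == 0) return(empty)

  ## candidate edges within the caliper, sparsified to nearest controls
  efrom <- eto <- integer(0)
  c_logit <- logit[c_idx]
  for (i in seq_len(nT)) {
    gap <- abs(c_logit - logit[t_idx[i]])
    ok <- which(gap <= cal)
    if (length(ok) > spec$max_candidates)
      ok <- ok[order(gap[ok], ok)[seq_len(spec$max_candidates)]]
    ok <- sort(ok)
    efrom <- c(efrom, rep.int(i, length(ok)))
    eto <- c(eto, ok)
  }
  if (!length(efrom)) return(empty)
  d <- sqrt(rowSums((Z[t_idx[efrom], , drop = FALSE] -
                       Z[c_idx[eto], , drop = FALSE])^2))
  int_cost <- round(d * spec$scale)

  ## fine-balance categories; targets are counts among all treated in block
  if (length(spec$fine_balance)) {
    cat_all <- interaction(cohort[spec$fine_balance], drop = FALSE,
                           lex.order = TRUE)
    t_cat <- as.integer(droplevels(cat_all[c(t_idx, c_idx)]))
    cats <- t_cat[seq_len(nT)]
    ccat <- t_cat[nT + seq_len(nC)]
    n_cat <- max(t_cat)
    target <- tabulate(cats, nbins = n_cat)
  } else {
    ccat <- rep(1L, nC); n_cat <- 1L; target <- nT
  }

  ## node layout: source, treated, controls, categories, sink
  src <- 0L
  t_node <- seq_len(nT)
  c_node <- nT + seq_len(nC)
  cat_node <- nT + nC + seq_len(n_cat)
  sink <- nT + nC + n_cat + 1L
  n_nodes <- sink + 1L
  penalty <- sum(int_cost) + 1

  from <- c(rep(src, nT), t_node[efrom], c_node,
            cat_node, cat_node)
  to <- c(t_node, c_node[eto], cat_node[ccat],
          rep(sink, n_cat), rep(sink, n_cat))
  cap <- c(rep(1L, nT), rep(1L, length(efrom)), rep(1L, nC),
           target, rep(nC, n_cat))
  cost <- c(rep(0, nT), int_cost, rep(0, nC),
            rep(0, n_cat), rep(penalty, n_cat))
  sol <- mcf_solve(n_nodes, from, to, cap, cost, src, sink)

  edge_rows <- nT + seq_along(efrom)  # positions of treated->control arcs
  used <- which(sol$flow[edge_rows] == 1)
  if (!length(used)) return(empty)
  sel_t <- t_idx[efrom[used]]
  sel_c <- c_idx[eto[used]]
  pairs <- data.frame(treated_id = cohort$patient_id[sel_t],
                      control_id = cohort$patient_id[sel_c],
                      distance = d[used], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$treated_id), , drop = FALSE]

  disc <- if (length(spec$fine_balance)) {
    matched_c <- tabulate(ccat[eto[used]], nbins = n_cat)
    sum(abs(target - matched_c))
  } else nT - length(used)
  list(pairs = pairs, discrepancy = disc)
}

## discrepancy contributed by a block with no pairs at all
fb_discrepancy_empty <- function(cohort, t_idx, spec) {
  length(t_idx)  # every treated category count is unmet
}
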