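test_that("Mahalanobis distance matches closed-form values", {
  s2 <- diag(2)
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), s2), 0)
  expect_equal(mahalanobis_distance(c(1, 0), c(0, 0), s2), 1)
  expect_equal(mahalanobis_distance(c(2, 1), c(0, 0), diag(c(4, 1))),
               sqrt(2), tolerance = 1e-7)
  ## symmetry
  expect_equal(mahalanobis_distance(c(3, -1), c(0.5, 2), s2),
               mahalanobis_distance(c(0.5, 2), c(3, -1), s2))
  ## indefinite matrix stays singular after the tiny ridge
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(mahalanobis_distance(c(1, 0), c(0, 0), bad), "singular")
})

test_that("standardized mean differences follow the pooled-variance formulas", {
  expect_equal(compute_smd(1, 1, 2, 2), 0)
  expect_equal(compute_smd(1, 0, 1, 1), 1)
  expect_equal(compute_smd(0.6, 0.5, type = "binary"),
               0.1 / sqrt(0.245), tolerance = 1e-12)
  expect_equal(compute_smd(0.3, 0.3, type = "binary"), 0)
  expect_equal(compute_smd(2, 2, 0, 0), 0)
  expect_error(compute_smd(1, 2, 0, 0), "zero pooled variance")
})

test_that("trivial matchings behave as expected", {
  inst <- random_match_instance(1, 1, seed = 5)
  spec <- match_spec(caliper = 10, mahal_covariates = c("x1", "x2"),
                     max_candidates = Inf)
  mp <- match_pairs(inst$cohort, inst$prop, spec)
  expect_equal(nrow(mp$pairs), 1)
  expect_equal(mp$n_unmatched_treated, 0)

  ## no admissible edges: empty matching with a warning, not an error
  inst$prop$logit <- c(10, -10)
  expect_warning(mp0 <- match_pairs(inst$cohort, inst$prop,
                                    match_spec(caliper = 0.1,
                                               mahal_covariates = c("x1", "x2"))),
                 "no admissible")
  expect_equal(nrow(mp0$pairs), 0)
})

test_that("a 2x2 cost structure yields the cheaper diagonal pairing", {
  ## one informative covariate: treated at 0 and 10, controls at 1 and 11,
  ## so cross pairings cost roughly ten times the diagonal ones
  co <- data.frame(patient_id = c("t1", "t2", "c1", "c2"),
                   treated = c(1, 1, 0, 0), x1 = c(0, 10, 1, 11),
                   x2 = 0, stringsAsFactors = FALSE)
  prop <- fake_propensity(rep(0, 4), c("x1"))
  mp <- match_pairs(co, prop, match_spec(caliper = 1,
                                         mahal_covariates = "x1"))
  expect_equal(mp$pairs$control_id[match(c("t1", "t2"),
                                         mp$pairs$treated_id)],
               c("c1", "c2"))
})

test_that("fine balance overrides raw distance when choosing controls", {
  ## treated categories {A, B}; controls {A, A, B}; the B control is far
  ## from everything, but near-fine balance must still select one A and
  ## the B control rather than the two (closer) A controls
  co <- data.frame(patient_id = c("tA", "tB", "cA1", "cA2", "cB"),
                   treated = c(1, 1, 0, 0, 0),
                   x1 = c(0, 10, 5, 10, 15),
                   cat = c("A", "B", "A", "A", "B"),
                   stringsAsFactors = FALSE)
  prop <- fake_propensity(rep(0, 5), "x1")
  mp <- match_pairs(co, prop,
                    match_spec(fine_balance = "cat", caliper = 1,
                               mahal_covariates = "x1"))
  expect_setequal(mp$pairs$control_id, c("cA1", "cB"))
  expect_equal(unname(mp$objective[["fine_balance"]]), 0)

  ## without fine balance the same instance picks the two nearest controls
  mp2 <- match_pairs(co, prop, match_spec(caliper = 1,
                                          mahal_covariates = "x1"))
  expect_setequal(mp2$pairs$control_id, c("cA1", "cA2"))
  expect_lt(mp2$objective[["distance"]], mp$objective[["distance"]])
})

test_that("every returned pair respects the caliper and exact constraints", {
  cfg <- cohort_config(n = c(low = 2500L, medium = 0L, high = 0L), seed = 31L)
  co <- impute_missing(apply_exclusions(generate_cohort(cfg))$cohort)
  p <- fit_propensity(co)
  spec <- match_spec(exact = "surgery_year", fine_balance = "admit_source",
                     caliper = 0.2)
  mp <- match_pairs(co, p, spec)
  expect_gt(nrow(mp$pairs), 0)
  it <- match(mp$pairs$treated_id, co$patient_id)
  ic <- match(mp$pairs$control_id, co$patient_id)
  expect_true(all(co$surgery_year[it] == co$surgery_year[ic]))
  expect_true(all(abs(p$logit[it] - p$logit[ic]) <=
                    0.2 * sd(p$logit) + 1e-12))
  expect_true(all(mp$pairs$distance >= 0))
  expect_false(any(duplicated(c(mp$pairs$treated_id, mp$pairs$control_id))))
  expect_true(all(co$treated[it] == 1) && all(co$treated[ic] == 0))
})

test_that("the flow solution equals exhaustive enumeration on small instances", {
  for (trial in 1:25) {
    nT <- sample(1:6, 1); nC <- sample(1:6, 1)
    inst <- random_match_instance(nT, nC, ncat = sample(1:3, 1),
                                  seed = 100 + trial)
    spec <- match_spec(fine_balance = "cat", caliper = 1,
                       mahal_covariates = c("x1", "x2"),
                       max_candidates = Inf)
    mp <- suppressWarnings(match_pairs(inst$cohort, inst$prop, spec))
    m <- instance_matrices(inst, caliper = 1)
    oracle <- enum_best_matching(m$adm, m$dist, m$tcat, m$ccat, m$ncat)
    expect_equal(unname(mp$objective[["pairs"]]), oracle[1], info = trial)
    expect_equal(unname(mp$objective[["fine_balance"]]), oracle[2],
                 info = trial)
    expect_equal(unname(mp$objective[["distance"]]), oracle[3],
                 tolerance = 1e-3, info = trial)
  }
})

test_that("relabeling record order leaves the optimal objective unchanged", {
  inst <- random_match_instance(5, 6, seed = 77)
  spec <- match_spec(fine_balance = "cat", caliper = 1,
                     mahal_covariates = c("x1", "x2"), max_candidates = Inf)
  mp1 <- match_pairs(inst$cohort, inst$prop, spec)
  set.seed(1); perm <- sample(nrow(inst$cohort))
  co2 <- inst$cohort[perm, ]
  prop2 <- inst$prop; prop2$logit <- prop2$logit[perm]
  prop2$fitted <- prop2$fitted[perm]
  mp2 <- match_pairs(co2, prop2, spec)
  expect_equal(mp1$objective, mp2$objective, tolerance = 1e-9)
})

test_that("match_spec rejects invalid configurations", {
  expect_error(match_spec(caliper = 0), "caliper")
  expect_error(match_spec(exact = "death"), "outcome")
})

test_that("post-match balance reaches the acceptable threshold on a moderate cohort", {
  cfg <- cohort_config(n = c(low = 6000L, medium = 0L, high = 0L), seed = 19L)
  co <- impute_missing(apply_exclusions(generate_cohort(cfg))$cohort)
  co <- teescore:::equalize_arms(co, 5L)
  p <- fit_propensity(co)
  mp <- match_pairs(co, p, match_spec(exact = "surgery_year",
                                      fine_balance = "admit_source"))
  b <- balance_report(co, mp)
  expect_true(all(b$smd_after < 0.10))
})
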