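fake_pairs <- function(treated_id, control_id) {
  structure(list(pairs = data.frame(treated_id = treated_id,
                                    control_id = control_id,
                                    distance = 0,
                                    stringsAsFactors = FALSE),
                 n_unmatched_treated = 0L,
                 objective = c(pairs = length(treated_id), fine_balance = 0,
                               distance = 0),
                 spec = match_spec()),
            class = "matched_pairs")
}

test_that("paired outcome tables tally concordant and discordant pairs", {
  co <- data.frame(patient_id = c("t1", "t2", "t3", "c1", "c2", "c3"),
                   death = c(1, 0, 0, 0, 1, 0), stringsAsFactors = FALSE)
  mp <- fake_pairs(c("t1", "t2", "t3"), c("c1", "c2", "c3"))
  pt <- pair_outcome_table(mp, co, "death")
  expect_equal(c(pt$a, pt$b, pt$c, pt$d), c(0, 1, 1, 1))
  expect_equal(pt$treated_events, pt$a + pt$b)
  expect_equal(pt$control_events, pt$a + pt$c)

  co$death <- 0
  pt0 <- pair_outcome_table(mp, co, "death")
  expect_equal(c(pt0$a, pt0$b, pt0$c, pt0$d), c(0, 0, 0, 3))
  expect_error(pair_outcome_table(mp, co, "nope"), "unknown outcome")

  ## 20-pair fixture against a hand tally
  set.seed(33)
  yt <- rbinom(20, 1, 0.4); yc <- rbinom(20, 1, 0.4)
  co20 <- data.frame(patient_id = c(sprintf("t%02d", 1:20),
                                    sprintf("c%02d", 1:20)),
                     death = c(yt, yc), stringsAsFactors = FALSE)
  mp20 <- fake_pairs(sprintf("t%02d", 1:20), sprintf("c%02d", 1:20))
  pt20 <- pair_outcome_table(mp20, co20, "death")
  expect_equal(pt20$b, sum(yt == 1 & yc == 0))
  expect_equal(pt20$c, sum(yt == 0 & yc == 1))
  expect_equal(pt20$a + pt20$b + pt20$c + pt20$d, 20)
})

test_that("paired risk difference and Wald interval match closed forms", {
  pt <- paired_table(n = 100, b = 10, c = 20)
  rd <- paired_risk_difference(pt)
  expect_equal(rd$rd, -10)
  half <- qnorm(0.975) * 100 * sqrt((10 + 20) - (10 - 20)^2 / 100) / 100
  expect_equal(rd$ci, c(-10 - half, -10 + half), tolerance = 1e-12)
  expect_equal(round(rd$ci, 2), c(-20.55, 0.55))

  expect_equal(paired_risk_difference(paired_table(50, 5, 5))$rd, 0)
  expect_error(paired_risk_difference(paired_table(0, 0, 0)), "at least one")

  ## RD from discordants equals RD from the per-arm marginals
  pt2 <- paired_table(200, b = 12, c = 30, a = 7)
  rd2 <- paired_risk_difference(pt2)
  expect_equal(rd2$rd,
               100 * (pt2$treated_events - pt2$control_events) / pt2$n)
})

test_that("the exact McNemar test equals binomial enumeration", {
  expect_equal(mcnemar_exact(paired_table(100, 5, 5)), 1)
  expect_equal(mcnemar_exact(paired_table(100, 1, 9)), 2 * 11 / 1024)
  expect_equal(mcnemar_exact(paired_table(100, 0, 5)), 0.0625)
  expect_warning(p0 <- mcnemar_exact(paired_table(10, 0, 0)),
                 "no discordant")
  expect_equal(p0, 1)
  for (b in c(0, 1, 3, 7)) for (cc in c(0, 2, 5, 11)) {
    if (b + cc == 0) next
    expect_equal(mcnemar_exact(paired_table(50, b, cc)),
                 mcnemar_brute(b, cc), info = paste(b, cc))
  }
})

test_that("the conditional OR and its exact limits match the Clopper-Pearson oracle", {
  expect_equal(conditional_odds_ratio(paired_table(50, 7, 7))$or, 1)
  r <- conditional_odds_ratio(paired_table(100, 5, 10))
  expect_equal(r$or, 0.5)
  bt <- as.numeric(binom.test(5, 15)$conf.int)
  expect_equal(r$ci, bt / (1 - bt), tolerance = 1e-8)

  r0 <- conditional_odds_ratio(paired_table(50, 0, 5))
  expect_equal(r0$or, 0)
  expect_equal(r0$ci[1], 0)
  rInf <- conditional_odds_ratio(paired_table(50, 5, 0))
  expect_equal(rInf$or, Inf)
  expect_equal(rInf$ci[2], Inf)
  expect_error(conditional_odds_ratio(paired_table(50, 0, 0)),
               "undefined")
})

test_that("BH adjustment reproduces the step-up definition in any order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))

  base <- c(0.002, 0.01, 0.03, 0.04, 0.2, 0.7)
  for (perm in all_permutations(seq_along(base))[c(1, 50, 200, 700)]) {
    p <- base[perm]
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("subgroup analysis has one row per score plus pooled, with additive counts", {
  set.seed(44)
  n <- 400
  co <- data.frame(patient_id = c(sprintf("t%03d", 1:n),
                                  sprintf("c%03d", 1:n)),
                   tee_score = rep(rep(1:5, length.out = n), 2),
                   death = rbinom(2 * n, 1, 0.1),
                   stringsAsFactors = FALSE)
  mp <- fake_pairs(sprintf("t%03d", 1:n), sprintf("c%03d", 1:n))
  res <- subgroup_analysis(co, mp, "death", stratum = "low")
  expect_equal(res$subgroup, c("pooled", "1", "2", "3", "4", "5"))
  expect_equal(res$n_pairs[1], sum(res$n_pairs[-1]))
  expect_equal(res$events_treated[1], sum(res$events_treated[-1]))
  expect_equal(res$events_control[1], sum(res$events_control[-1]))
  ## BH within the six rows, per effect-measure family
  expect_equal(res$p_rd_bh, bh_adjust(res$p_rd))
  expect_equal(res$p_or_bh, bh_adjust(res$p_or))
  ## empty subgroup flagged, not fatal
  co2 <- co; co2$tee_score[co2$tee_score == 5] <- 4
  res2 <- subgroup_analysis(co2, mp, "death", stratum = "low")
  expect_equal(res2$n_pairs[res2$subgroup == "5"], 0)
  expect_true(res2$unstable[res2$subgroup == "5"])
})

test_that("the paired Wald interval covers a null risk difference at its nominal rate", {
  set.seed(55)
  reps <- 200
  cover <- logical(reps)
  for (i in seq_len(reps)) {
    yt <- rbinom(500, 1, 0.03); yc <- rbinom(500, 1, 0.03)
    pt <- paired_table(500, b = sum(yt == 1 & yc == 0),
                       c = sum(yt == 0 & yc == 1),
                       a = sum(yt == 1 & yc == 1))
    ci <- paired_risk_difference(pt)$ci
    cover[i] <- ci[1] <= 0 && ci[2] >= 0
  }
  expect_lt(abs(mean(cover) - 0.95), 3 * sqrt(0.95 * 0.05 / reps))
})
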