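test_that("the stratified split is disjoint, exhaustive and reproducible", {
  cfg <- cohort_config(n = c(low = 1000L, medium = 1000L, high = 1000L),
                       seed = 2L)
  co <- generate_cohort(cfg)
  sp <- split_train_test(co, 0.25, seed = 9L)
  for (s in c("low", "medium", "high")) {
    expect_equal(sum(sp$train$volume_stratum == s), 250)
    expect_equal(sum(sp$test$volume_stratum == s), 750)
  }
  sp2 <- split_train_test(co, 0.25, seed = 9L)
  expect_identical(sp, sp2)

  small <- co[1:50, ]
  spl <- split_train_test(small, 0.3, seed = 4L)
  expect_setequal(c(spl$train$patient_id, spl$test$patient_id),
                  small$patient_id)
  expect_length(intersect(spl$train$patient_id, spl$test$patient_id), 0)

  co$volume_stratum <- factor(co$volume_stratum,
                              levels = c("low", "medium", "high", "huge"))
  expect_error(split_train_test(co, 0.25, 1L), "huge")
  expect_error(split_train_test(co, 0, 1L), "fraction")
})

simulate_cate_data <- function(n, beta, seed) {
  set.seed(seed)
  d <- data.frame(treated = rbinom(n, 1, 0.5),
                  ef = rnorm(n, 52, 12), chf = rbinom(n, 1, 0.2),
                  creatinine = exp(rnorm(n, 0.1, 0.4)),
                  left_main_gt50 = rbinom(n, 1, 0.32),
                  vessels_ge3 = rbinom(n, 1, 0.77),
                  inotrope_48h = rbinom(n, 1, 0.05))
  X <- cbind(1, teescore:::cate_design(d))
  d$death <- rbinom(n, 1, plogis(drop(X %*% beta)))
  d
}

true_beta <- function(intercept = -3.7, treated = -0.2, ef = -0.02,
                      chf = 0.3, creat = 0.3, lm = 0.1, v3 = 0.15,
                      ino = 0.8, i_ef = 0, i_chf = 0, i_creat = 0,
                      i_lm = 0, i_v3 = 0, i_ino = 0) {
  c(intercept, treated, ef, chf, creat, lm, v3, ino,
    i_ef, i_chf, i_creat, i_lm, i_v3, i_ino)
}

test_that("the CATE model recovers known coefficients and matches a second optimizer", {
  beta <- true_beta(treated = 0.1, i_lm = -0.6, i_v3 = -0.4, i_ino = -0.8)
  d <- simulate_cate_data(50000, beta, seed = 14L)
  m <- fit_cate_model(d)
  oracle <- nr_logistic(teescore:::cate_design(d), d$death)
  expect_equal(unname(m$coefficients), unname(oracle$coef),
               tolerance = 1e-6)
  se <- sqrt(diag(oracle$vcov))
  expect_true(all(abs(m$coefficients - beta) < 3 * se))
})

test_that("null interactions are estimated near zero", {
  d <- simulate_cate_data(50000, true_beta(), seed = 15L)
  m <- fit_cate_model(d)
  oracle <- nr_logistic(teescore:::cate_design(d), d$death)
  se <- sqrt(diag(oracle$vcov))
  idx <- grep("^treated:", names(m$coefficients))
  expect_true(all(abs(m$coefficients[idx]) < 3 * se[idx]))
})

test_that("CATE predictions follow the inverse-logit arithmetic", {
  m <- structure(list(coefficients = setNames(rep(0, 14),
    c("(Intercept)", "treated", teescore::tee_modifiers,
      paste0("treated:", teescore::tee_modifiers))),
    stratum = "low", n = 0L, iterations = 0L), class = "cate_model")
  rec <- data.frame(ef = 50, chf = 0, creatinine = 1, left_main_gt50 = 0,
                    vessels_ge3 = 0, inotrope_48h = 0)
  expect_equal(predict_cate(m, rec), 0)

  m$coefficients["treated"] <- -0.5
  expect_equal(predict_cate(m, rec), plogis(-0.5) - 0.5,
               tolerance = 1e-12)
  m$coefficients["treated"] <- 0.5
  expect_equal(predict_cate(m, rec), -(plogis(-0.5) - 0.5),
               tolerance = 1e-12)
  expect_error(predict_cate(m, rec[, -1, drop = FALSE]), "modifier")
  rec$ef <- NA
  expect_error(predict_cate(m, rec), "missing")
})

test_that("quintile scores are equal-frequency, monotone, and reuse training cutpoints", {
  r <- assign_tee_score(c(-.05, -.04, -.03, -.02, -.01))
  expect_equal(r$score, 1:5)

  set.seed(6)
  v <- sample(seq(-0.1, 0.1, length.out = 10))
  r10 <- assign_tee_score(v)
  expect_equal(as.integer(table(r10$score)), rep(2L, 5))
  ## monotone: sorting by CATE sorts the score
  o <- order(v)
  expect_true(all(diff(r10$score[o]) >= 0))

  ## equal-frequency on a larger tie-free sample
  big <- rnorm(1000)
  rb <- assign_tee_score(big)
  expect_equal(as.integer(table(rb$score)), rep(200L, 5))

  ## cutpoints from training applied unchanged to new records
  test_scores <- assign_tee_score(big, c(-10, 10, big[17]))$score
  expect_equal(test_scores[1:2], c(1L, 5L))
  expect_equal(test_scores[3], rb$score[17])

  expect_warning(rall <- assign_tee_score(rep(0.01, 6)), "identical")
  expect_true(all(rall$score == 1))
  expect_error(assign_tee_score(c(-1, 1)), "at least 5")
})

test_that("score derivation recovers concentrated benefit end to end", {
  ## strong benefit confined to the flagged phenotype; the estimated score
  ## ordering must reproduce the true CATE ordering on average
  beta <- true_beta(treated = 0, i_ef = 0.015, i_lm = -0.7, i_v3 = -0.5,
                    i_ino = -1.0)
  d <- simulate_cate_data(60000, beta, seed = 16L)
  m <- fit_cate_model(d)
  cates <- predict_cate(m, d)
  d$tee_score <- assign_tee_score(cates)$score
  X <- cbind(1, teescore:::cate_design(transform(d, treated = 1)))
  X0 <- cbind(1, teescore:::cate_design(transform(d, treated = 0)))
  true_cate <- plogis(drop(X %*% beta)) - plogis(drop(X0 %*% beta))
  means <- tapply(true_cate, d$tee_score, mean)
  expect_length(means, 5)
  expect_true(all(diff(means) > 0))
})
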