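make_clean_records <- function(n) {
  data.frame(patient_id = sprintf("c%02d", seq_len(n)),
             hospital_id = "H1", treated = rep_len(c(1, 0), n),
             concomitant_procedure = 0, vessels_ge3 = 1,
             operative_status = "urgent", stringsAsFactors = FALSE)
}

test_that("each exclusion rule removes exactly its violators", {
  co <- make_clean_records(10)
  co$treated[1] <- NA                      # missing TEE
  co$concomitant_procedure[2] <- 1         # concomitant non-CABG procedure
  co$hospital_id[3] <- NA                  # missing hospital
  co$vessels_ge3[4] <- NA                  # missing vessel count
  co$operative_status[5] <- "emergent_salvage"
  res <- apply_exclusions(co)
  expect_equal(nrow(res$cohort), 5)
  counts <- setNames(res$report$n, res$report$rule)
  expect_equal(unname(counts[c("missing_tee", "concomitant_procedure",
                               "missing_hospital", "missing_vessels",
                               "salvage_or_unknown_status")]),
               rep(1, 5))
  expect_equal(sum(res$report$n), nrow(co))
})

test_that("a record violating several rules is counted once, under the first", {
  co <- make_clean_records(4)
  co$treated[1] <- NA
  co$operative_status[1] <- "unknown"      # also violates the status rule
  res <- apply_exclusions(co)
  counts <- setNames(res$report$n, res$report$rule)
  expect_equal(unname(counts["missing_tee"]), 1)
  expect_equal(unname(counts["salvage_or_unknown_status"]), 0)
})

test_that("exclusions are the identity on a clean cohort and preserve row order", {
  co <- make_clean_records(8)
  res <- apply_exclusions(co)
  expect_identical(res$cohort, co)
  co2 <- make_clean_records(8)
  co2$treated[3] <- NA
  kept <- apply_exclusions(co2)$cohort
  expect_identical(kept$patient_id, co2$patient_id[-3])
})

test_that("operative status emergent salvage or unknown is excluded", {
  co <- make_clean_records(3)
  co$operative_status <- c("urgent", "emergent_salvage", "unknown")
  res <- apply_exclusions(co)
  expect_equal(res$cohort$patient_id, "c01")
})

test_that("imputation fills continuous gaps with the median and categorical with the mode", {
  d <- data.frame(patient_id = letters[1:4], x = c(1, 2, NA, 4),
                  g = c("A", "A", NA, "B"), b = c(0, 0, NA, 1),
                  stringsAsFactors = FALSE)
  out <- impute_missing(d)
  expect_equal(out$x[3], 2)       # median of {1, 2, 4}
  expect_equal(out$g[3], "A")     # mode
  expect_equal(out$b[3], 0)       # 0/1 column imputed by mode, not median
  expect_false(anyNA(out))

  clean <- impute_missing(d[1:2, ])
  expect_identical(clean, d[1:2, ])
  d$x <- NA_real_
  expect_error(impute_missing(d), "entirely missing")
})

test_that("volume thresholds partition annual case counts", {
  expect_equal(as.character(assign_volume_stratum(c(1, 99, 100, 175, 250,
                                                    251, 800))),
               c("low", "low", "medium", "medium", "medium", "high", "high"))
  expect_error(assign_volume_stratum(0), "positive")
  expect_error(assign_volume_stratum(NA), "positive")
})

test_that("baseline summaries match hand arithmetic", {
  d <- data.frame(treated = c(1, 1, 0, 0), age = c(60, 70, 50, 80),
                  race = c("w", "b", "w", "w"), stringsAsFactors = FALSE)
  tb <- summarize_baseline(d, covariates = c("age", "race"))
  a1 <- tb[tb$variable == "age" & tb$group == "treated=1", ]
  expect_equal(a1$mean, 65)
  expect_equal(a1$sd, sd(c(60, 70)))
  rw <- tb[tb$variable == "race" & tb$level == "w" & tb$group == "overall", ]
  expect_equal(rw$count, 3)
  expect_equal(rw$pct, 75)

  ## two identical groups summarize identically
  d2 <- data.frame(treated = c(1, 0), age = c(55, 55))
  w <- capture_warnings(tb2 <- summarize_baseline(d2, covariates = "age"))
  expect_match(w, "SD reported as 0", all = TRUE)
  expect_length(w, 2)   # one per single-record group
  expect_equal(tb2$mean[tb2$group == "treated=1"],
               tb2$mean[tb2$group == "treated=0"])
  expect_equal(tb2$sd[tb2$group == "treated=1"], 0)

  expect_error(summarize_baseline(d, group = "nope"), "grouping column")
  expect_error(summarize_baseline(d[0, ]), "empty")
})
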