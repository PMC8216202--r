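test_that("trial filter drops block 1 and out-of-window response times", {
  tr <- data.frame(block = rep(1:6, each = 16), rt_ms = 800)
  tr$rt_ms[c(20, 40)] <- c(100, 6000)
  out <- filter_trials(tr)
  expect_equal(nrow(out), 96 - 16 - 2)
  expect_false(any(out$block == 1))

  clean <- data.frame(block = rep(1:6, each = 16), rt_ms = 800)
  expect_equal(nrow(filter_trials(clean)), 80)  # 96 - 96/6

  # idempotent, order-preserving, input untouched
  once <- filter_trials(tr)
  expect_identical(filter_trials(once), once)
  expect_false(is.unsorted(as.integer(rownames(once))))
  expect_equal(nrow(tr), 96)
  expect_error(filter_trials(data.frame(rt_ms = 1)), "block")
})

make_part <- function(n = 80, acc = 0.8, rt = 800, block = 2L) {
  n_cor <- round(n * acc)
  data.frame(participant_id = "P1", block = block, trial = seq_len(n),
             stimulus = "S1",
             response = rep(c("S1", "S2"), length.out = n),
             correct = rep(c(TRUE, FALSE), c(n_cor, n - n_cor)),
             confidence = 0.5, rt_ms = rt,
             stringsAsFactors = FALSE)
}

test_that("participant rejection rules flag the registered reasons", {
  # accuracy below 60%
  p <- make_part(acc = 0.55)
  p$response <- rep(c("S1", "S2"), each = 40)  # errors of both types
  r <- participant_exclusion(p, comprehension_pass = TRUE)
  expect_true(r$excluded)
  expect_match(r$reasons, "low_accuracy")

  # >25% of ALL trials outside the RT window (even if analysed trials fine)
  p <- make_part(n = 100, acc = 0.8)
  p$rt_ms[1:30] <- 200
  r <- participant_exclusion(p, comprehension_pass = TRUE)
  expect_true(r$excluded)
  expect_match(r$reasons, "rt_violations")

  # one error among S1 responses, many among S2 -> too few errors
  p <- make_part(n = 80, acc = 0.8)
  p$response <- "S2"
  p$response[p$correct][1:35] <- "S1"   # 35 correct S1 responses
  p$response[!p$correct][1] <- "S1"     # a single S1 error
  r <- participant_exclusion(p, comprehension_pass = TRUE)
  expect_true(r$excluded)
  expect_match(r$reasons, "too_few_errors")

  # comprehension failure alone excludes
  p <- make_part()
  p$response <- rep(c("S1", "S2"), length.out = 80)
  r <- participant_exclusion(p, comprehension_pass = FALSE)
  expect_match(r$reasons, "comprehension_fail")

  # a compliant participant survives
  p <- make_part(acc = 0.75)
  p$response <- rep(c("S1", "S2"), length.out = 80)
  r <- participant_exclusion(p, comprehension_pass = TRUE)
  expect_false(r$excluded)
  expect_identical(r$reasons, "")

  expect_error(participant_exclusion(make_part()[0, ]), "empty")
})

test_that("exclusion decisions are invariant to trial order", {
  p <- make_part(n = 96, acc = 0.58, block = rep(1:6, each = 16))
  p$response <- rep(c("S1", "S2"), length.out = 96)
  set.seed(4)
  shuffled <- p[sample(nrow(p)), ]
  a <- participant_exclusion(p, TRUE)
  b <- participant_exclusion(shuffled, TRUE)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("toy participant summary matches hand-computed values", {
  s <- summarize_participant(with_correct(toy_trials()))
  expect_equal(s$mean_conf_s1, 0.65)
  expect_equal(s$mean_conf_s2, 0.575)
  expect_equal(s$auroc_s1, 1.0)
  expect_equal(s$auroc_s2, 0.75)      # 6 of 8 concordant pairs
  expect_equal(s$delta_auc, s$auroc_s1 - s$auroc_s2)
  # matched equal-variance quantities, frozen from an independent
  # normal-quantile / trapezoid computation (d' = 0.8614546, c = 0; the
  # unbiased criterion makes the two model curves mirror images, so the
  # matched asymmetry vanishes exactly)
  expect_equal(s$auroc_hat_s1, 0.593353210259773, tolerance = 1e-9)
  expect_equal(s$auroc_hat_s2, 0.593353210259773, tolerance = 1e-9)
  expect_equal(s$matched_delta_auc, 0, tolerance = 1e-12)
  expect_equal(s$asymmetry_beyond_sdt, 0.25, tolerance = 1e-12)
  expect_equal(s$mean_log_rt_s1, mean(log(seq(500, 1000, by = 100))))
  expect_equal(s$mean_log_rt_s2, mean(log(seq(1100, 1600, by = 100))))
})

test_that("identical confidences give equal mean confidence per response", {
  p <- with_correct(toy_trials())
  p$confidence <- 0.5
  s <- suppressWarnings(summarize_participant(p))
  expect_equal(s$mean_conf_s1, s$mean_conf_s2)
})

test_that("default synthetic population loses fewer than 20% of participants", {
  tr <- simulate_cohort(100, seed = 303)
  rep <- exclusion_report(tr)
  expect_lt(mean(rep$excluded), 0.20)
})
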