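test_that("staircase follows the 1-up-2-down rule", {
  s <- staircase_update(staircase_state(30, 1), TRUE)
  expect_equal(s$soa_ms, 27)
  expect_equal(s$consecutive_correct, 0L)

  s <- staircase_update(staircase_state(27, 0), FALSE)
  expect_equal(s$soa_ms, 30)
  expect_equal(s$consecutive_correct, 0L)

  s <- staircase_update(staircase_state(30, 0), TRUE)
  expect_equal(s$soa_ms, 30)
  expect_equal(s$consecutive_correct, 1L)
})

test_that("staircase converges to ~70.7% accuracy for a stationary observer", {
  set.seed(101)
  obs <- observer_params(sigma_s1 = 1, lapse_rate = 0)
  cfg <- experiment_config(n_trials = 20000L, n_blocks = 1L)
  tr <- simulate_participant("P001", obs, cfg)
  acc <- mean(tr$correct[tr$trial > 500])  # drop burn-in from the 30 ms start
  expect_gt(acc, 0.687)
  expect_lt(acc, 0.727)
})

test_that("SOA-to-sensitivity link is zero at zero, half at half-point, monotone", {
  obs <- observer_params()
  expect_equal(psychometric_dprime(0, obs), 0)
  expect_equal(psychometric_dprime(obs$soa_half_point_ms, obs),
               obs$dprime_max / 2)
  soa <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(psychometric_dprime(soa, obs)) > 0))
  expect_true(all(psychometric_dprime(2 * soa, obs) >
                    psychometric_dprime(soa, obs)))
  expect_error(psychometric_dprime(-1, obs), "non-negative")
})

test_that("trial generation respects the evidence rule", {
  set.seed(7)
  tr <- replicate(50, simulate_trial(staircase_state(30),
                                     observer_params())$confidence)
  expect_true(all(tr >= 0 & tr <= 1))

  # widely separated distributions, no lapses: near-perfect accuracy
  obs <- observer_params(sigma_s1 = 1, criterion_c = 2.5, lapse_rate = 0,
                         dprime_max = 5)
  set.seed(8)
  st <- simulate_stationary(5000, dprime = 5, obs)
  expect_gt(mean(st$correct), 0.98)
})

test_that("unequal variance produces the type-2 asymmetry", {
  set.seed(31)
  obs <- observer_params(sigma_s1 = 1.5, criterion_c = 0.75,
                         conf_noise_sd = 0, lapse_rate = 0)
  tr <- simulate_stationary(2e5, dprime = 1.5, obs)
  d <- delta_auc(tr)
  expect_gt(d$auroc_s1, d$auroc_s2)
})

test_that("cohort simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(3, seed = 5)
  b <- simulate_cohort(3, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 96)
  expect_true(all(tapply(a$comprehension_pass, a$participant_id,
                         function(v) length(unique(v)) == 1L)))
})

test_that("equal-variance noise-free observers give dAUC symmetric about zero", {
  # stationary observers with the criterion at the distribution midpoint:
  # the two response conditions are mirror images, so participant dAUC
  # must be symmetric about 0
  set.seed(202)
  obs <- observer_params(sigma_s1 = 1, criterion_c = 0.545,
                         conf_noise_sd = 0, lapse_rate = 0)
  d <- replicate(1000, {
    tr <- simulate_stationary(80, 1.09, obs)
    tryCatch(delta_auc(tr)$delta, error = function(e) NA_real_)
  })
  d <- d[!is.na(d) & d != 0]
  st <- stats::binom.test(sum(d > 0), length(d))
  expect_gt(st$p.value, 0.01)
})

test_that("staircased equal-variance cohorts keep group dAUC near zero", {
  # the staircase makes sensitivity drift between trials, which leaves a
  # small positive dAUC even at sigma_s1 = 1; it stays an order of
  # magnitude below the unequal-variance effect
  pop <- cohort_population(sigma_s1_mean = 1, sigma_s1_sd = 0,
                           conf_noise_mean = 0, criterion_sd = 0,
                           comprehension_rate = 1, lapse_rate = 0)
  tr <- simulate_cohort(300, population = pop, seed = 203)
  d <- participant_summaries(tr)$summaries$delta_auc
  expect_lt(abs(mean(d)), 0.05)
})

test_that("accuracy is invariant to joint S1/S2 relabelling with c -> d' - c", {
  obs_a <- observer_params(sigma_s1 = 1, criterion_c = 0.3, lapse_rate = 0)
  obs_b <- observer_params(sigma_s1 = 1, criterion_c = 1.1 - 0.3,
                           lapse_rate = 0)
  set.seed(77)
  acc_a <- mean(simulate_stationary(2e5, 1.1, obs_a)$correct)
  acc_b <- mean(simulate_stationary(2e5, 1.1, obs_b)$correct)
  se <- sqrt(0.25 / 2e5)
  expect_lt(abs(acc_a - acc_b), 4 * sqrt(2) * se)
})
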