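sdt_trials <- function(n_s1, n_s2, k_hit, k_fa) {
  data.frame(
    stimulus = rep(c("S1", "S2"), c(n_s1, n_s2)),
    response = c(rep(c("S1", "S2"), c(k_hit, n_s1 - k_hit)),
                 rep(c("S1", "S2"), c(k_fa, n_s2 - k_fa))),
    stringsAsFactors = FALSE)
}

test_that("equal-variance SDT estimates match the probit formulas", {
  # hr = far -> d' = 0
  f <- estimate_sdt(sdt_trials(10, 10, 4, 4))
  expect_equal(f$dprime, 0)

  # hr = 0.8, far = 0.3: z(0.8) = 0.8416, z(0.3) = -0.5244
  f <- estimate_sdt(sdt_trials(10, 10, 8, 3))
  expect_equal(f$dprime, qnorm(0.8) - qnorm(0.3))
  expect_equal(f$dprime, 1.3660, tolerance = 1e-4)
  expect_equal(f$criterion_c, -0.1586, tolerance = 1e-4)

  # joint relabelling keeps d', reflects the criterion about the midpoint
  tr <- sdt_trials(20, 20, 15, 4)
  sw <- tr
  sw$stimulus <- ifelse(tr$stimulus == "S1", "S2", "S1")
  sw$response <- ifelse(tr$response == "S1", "S2", "S1")
  a <- estimate_sdt(tr); b <- estimate_sdt(sw)
  expect_equal(b$dprime, a$dprime)
  expect_equal(b$criterion_c, -a$criterion_c)

  expect_error(estimate_sdt(data.frame(stimulus = "S1", response = "S1")),
               "both stimulus classes")
})

test_that("extreme rates are pulled inside the unit interval", {
  f <- estimate_sdt(sdt_trials(10, 10, 10, 0))
  expect_equal(f$hr, 1 - 1 / 20)
  expect_equal(f$far, 1 / 20)
  f2 <- estimate_sdt(sdt_trials(10, 10, 10, 0), correction = "loglinear")
  expect_equal(f2$hr, 10.5 / 11)
  expect_equal(f2$far, 0.5 / 11)
})

test_that("expected type-2 curves are proper ROC curves", {
  p <- seq(0, 1, length.out = 41)
  for (fit in list(make_fit(0, 0), make_fit(1.366, -0.159),
                   make_fit(2, 0.6), make_fit(0.5, -0.8))) {
    for (resp in c("S1", "S2")) {
      hr <- expected_type2_hr(p, resp, fit)
      expect_equal(hr[1], 0)
      expect_equal(hr[length(hr)], 1)
      expect_true(all(diff(hr) >= -1e-12))
      expect_true(all(hr >= 0 & hr <= 1))
    }
  }
  # zero sensitivity puts both curves on the diagonal
  expect_equal(expected_type2_hr(p, "S1", make_fit(0, 0.4)), p,
               tolerance = 1e-12)
  expect_equal(expected_type2_hr(p, "S2", make_fit(0, 0.4)), p,
               tolerance = 1e-12)
  # above the diagonal when there is signal
  fit <- make_fit(1.2, 0.2)
  mid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(expected_type2_hr(mid, "S1", fit) >= mid))
  expect_error(expected_type2_hr(1.2, "S1", fit), "0, 1")
})

test_that("unbiased criteria make the two model curves mirror images", {
  fit <- make_fit(1.4, 0)  # criterion at the distribution midpoint
  p <- seq(0, 1, length.out = 31)
  expect_equal(expected_type2_hr(p, "S1", fit),
               expected_type2_hr(p, "S2", fit), tolerance = 1e-12)
})

test_that("expected type-2 hit rate matches a Monte-Carlo observer", {
  fit <- make_fit(1.366, -0.159)
  set.seed(21)
  n <- 1e6
  x1 <- rnorm(n, fit$dprime, 1)       # S1 on the 0/d' axis
  x2 <- rnorm(n, 0, 1)
  c_axis <- fit$criterion_c + fit$dprime / 2
  correct <- x1[x1 > c_axis]          # correct S1 responses
  incorrect <- x2[x2 > c_axis]        # incorrect S1 responses
  theta <- quantile(incorrect, 0.5)   # conf monotone in evidence here
  mc <- mean(correct > theta)
  se <- sqrt(mc * (1 - mc) / length(correct))
  expect_lt(abs(expected_type2_hr(0.5, "S1", fit) - mc), 3 * se)
})

test_that("matched asymmetry vanishes for a zero-sensitivity participant", {
  set.seed(22)
  n <- 400
  tr <- data.frame(stimulus = sample(c("S1", "S2"), n, TRUE),
                   response = sample(c("S1", "S2"), n, TRUE),
                   confidence = runif(n), stringsAsFactors = FALSE)
  tr$correct <- tr$stimulus == tr$response
  fit <- estimate_sdt(tr)
  hat <- matched_delta_auc(tr, make_fit(0, fit$criterion_c))
  expect_equal(hat$auroc_hat_s1, 0.5, tolerance = 1e-12)
  expect_equal(hat$auroc_hat_s2, 0.5, tolerance = 1e-12)
  expect_equal(hat$delta_hat, 0, tolerance = 1e-12)
})

test_that("the control absorbs bias-induced asymmetry under equal variance", {
  # an equal-variance observer with a conservative criterion shows a
  # nonzero empirical dAUC, but the matched model reproduces it
  obs <- observer_params(sigma_s1 = 1, criterion_c = 0.85,
                         conf_noise_sd = 0, lapse_rate = 0)
  set.seed(23)
  vals <- replicate(8, asymmetry_beyond_sdt(simulate_stationary(1e5, 1.1, obs)))
  deltas <- replicate(8, delta_auc(simulate_stationary(1e5, 1.1, obs))$delta)
  expect_gt(abs(mean(deltas)), 4 * sd(deltas) / sqrt(8))  # bias asymmetry real
  expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(8))      # control removes it
})

test_that("asymmetry beyond SDT is positive under unequal variance", {
  obs <- observer_params(sigma_s1 = 1.5, criterion_c = 0.75,
                         conf_noise_sd = 0, lapse_rate = 0)
  set.seed(24)
  vals <- replicate(6, asymmetry_beyond_sdt(simulate_stationary(5e4, 1.5, obs)))
  expect_gt(mean(vals), 5 * sd(vals) / sqrt(6))
})

test_that("asymmetry beyond SDT flips sign under response relabelling", {
  tr <- with_correct(toy_trials())
  sw <- tr
  sw$stimulus <- ifelse(tr$stimulus == "S1", "S2", "S1")
  sw$response <- ifelse(tr$response == "S1", "S2", "S1")
  expect_equal(asymmetry_beyond_sdt(sw), -asymmetry_beyond_sdt(tr),
               tolerance = 1e-12)
})
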