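#' Fit the equal-variance SDT model to choice data
#'
#' Estimates sensitivity d' and criterion c from one participant's
#' stimulus/response table under the equal-variance Gaussian model:
#' `d' = z(HR) - z(FAR)` and `c = -(z(HR) + z(FAR)) / 2`, where HR is the
#' probability of responding S1 to stimulus S1 and FAR the probability of
#' responding S1 to stimulus S2. Rates of exactly 0 or 1 are pulled inside
#' the unit interval before the probit transform.
#'
#' @param trials Trial `data.frame` with columns `stimulus`, `response`
#'   (values `"S1"`/`"S2"`); both stimulus classes must be present.
#' @param correction Extreme-rate correction: `"half"` replaces 0 with
#'   `1/(2N)` and 1 with `1 - 1/(2N)` (N the class size); `"loglinear"` uses
#'   `(k + 0.5) / (N + 1)` for every rate.
#' @return An object of class `"sdt_fit"`: list with `dprime`,
#'   `criterion_c`, `hr`, `far`, `n_s1`, `n_s2`.
#' @examples
#' tr <- data.frame(stimulus = rep(c("S1", "S2"), each = 10),
#'                  response = rep(c("S1", "S2", "S1", "S2"), c(8, 2, 3, 7)))
#' estimate_sdt(tr)
#' @export
estimate_sdt <- function(trials, correction = c("half", "loglinear")) {
  correction <- match.arg(correction)
  .check_columns(trials, c("stimulus", "response"))
  n_s1 <- sum(trials$stimulus == "S1")
  n_s2 <- sum(trials$stimulus == "S2")
  if (n_s1 == 0L || n_s2 == 0L)
    stop("both stimulus classes must be present to fit the SDT model")
  k_hit <- sum(trials$stimulus == "S1" & trials$response == "S1")
  k_fa <- sum(trials$stimulus == "S2" & trials$response == "S1")
  rate <- function(k, n) {
    if (correction == "loglinear") return((k + 0.5) / (n + 1))
    p <- k / n
    if (p == 0) p <- 1 / (2 * n)
    if (p == 1) p <- 1 - 1 / (2 * n)
    p
  }
  hr <- rate(k_hit, n_s1)
  far <- rate(k_fa, n_s2)
  structure(list(dprime = stats::qnorm(hr) - stats::qnorm(far),
                 criterion_c = -0.5 * (stats::qnorm(hr) + stats::qnorm(far)),
                 hr = hr, far = far, n_s1 = n_s1, n_s2 = n_s2),
            class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat(sprintf(
    "Equal-variance SDT fit: d' = %.3f, c = %.3f (HR %.3f, FAR %.3f; n = %d + %d)\n",
    x$dprime, x$criterion_c, x$hr, x$far, x$n_s1, x$n_s2))
  invisible(x)
}

#' Model-expected type-2 hit rate of the matched equal-variance observer
#'
#' For an equal-variance SDT observer with the fitted d' and c whose
#' confidence is any monotone function of the distance between evidence and
#' criterion, the type-2 ROC has a closed form. The fitted criterion is
#' measured from the midpoint between the two evidence distributions
#' (standard convention) and is shifted internally to the axis with S2 at 0
#' and S1 at d'. For S1 responses (evidence above criterion) the type-2
#' criterion `theta >= c` reproducing a cumulative incorrect proportion
#' `p_far` satisfies `P(x > theta | S2) = p_far * P(x > c | S2)`, inverted
#' exactly with the normal quantile function; the expected cumulative
#' correct proportion is then `P(x > theta | S1) / P(x > c | S1)`. S2
#' responses use the mirror construction on the lower tails. The map is
#' monotone with `0 -> 0` and `1 -> 1`, so the model curve is a proper ROC.
#'
#' @param p_far Cumulative proportion(s) of incorrect trials, in \[0, 1\]
#'   (vectorised).
#' @param response `"S1"` or `"S2"`.
#' @param fit An `"sdt_fit"` object.
#' @return Expected cumulative correct proportion(s), same length as
#'   `p_far`.
#' @export
expected_type2_hr <- function(p_far, response = c("S1", "S2"), fit) {
  response <- match.arg(response)
  stopifnot(inherits(fit, "sdt_fit"))
  if (any(p_far < 0 | p_far > 1)) stop("'p_far' must lie in [0, 1]")
  d <- fit$dprime
  ## criterion_c is measured from the midpoint of the two distributions;
  ## shift to the axis with S2 at 0 and S1 at d'
  cc <- fit$criterion_c + d / 2
  if (response == "S1") {
    ## incorrect S1 responses: S2 trials with x > c
    tail_inc <- stats::pnorm(cc, lower.tail = FALSE)
    tail_cor <- stats::pnorm(cc, mean = d, lower.tail = FALSE)
    theta <- stats::qnorm(p_far * tail_inc, lower.tail = FALSE)
    hr <- stats::pnorm(theta, mean = d, lower.tail = FALSE) / tail_cor
  } else {
    ## incorrect S2 responses: S1 trials with x < c
    tail_inc <- stats::pnorm(cc, mean = d)
    tail_cor <- stats::pnorm(cc)
    theta <- stats::qnorm(p_far * tail_inc, mean = d)
    hr <- stats::pnorm(theta) / tail_cor
  }
  ## p_far = 0 gives theta = +/-Inf and hr 0/tail -> 0; clamp rounding spill
  pmin(1, pmax(0, hr))
}

#' SDT-matched metacognitive asymmetry
#'
#' The response-conditional ROC asymmetry expected from an equal-variance
#' SDT observer matched to the participant: same sensitivity and response
#' bias (from [estimate_sdt()]) and the same distribution of confidence in
#' incorrect responses. For each response, the participant's empirical
#' cumulative incorrect-confidence proportions serve as x values and are
#' mapped through [expected_type2_hr()]; the area under the resulting model
#' curve is taken by the trapezoidal rule.
#'
#' @param trials One participant's filtered trial `data.frame` with columns
#'   `stimulus`, `response`, `correct`, `confidence`.
#' @param fit Optional pre-computed `"sdt_fit"`; estimated from `trials`
#'   when missing.
#' @return A list with `auroc_hat_s1`, `auroc_hat_s2`, `delta_hat`, and the
#'   model curves as `"roc2"` objects (`roc_hat_s1`, `roc_hat_s2`).
#' @export
matched_delta_auc <- function(trials, fit = NULL) {
  .check_columns(trials, c("stimulus", "response", "correct", "confidence"))
  if (is.null(fit)) fit <- estimate_sdt(trials)
  emp <- delta_auc(trials)
  hat <- lapply(c(S1 = "S1", S2 = "S2"), function(r) {
    curve <- if (r == "S1") emp$roc_s1 else emp$roc_s2
    hr_hat <- expected_type2_hr(curve$far, r, fit)
    structure(list(far = curve$far, hr = hr_hat,
                   area = trapezoid_area(curve$far, hr_hat),
                   response = r, n_correct = curve$n_correct,
                   n_incorrect = curve$n_incorrect),
              class = "roc2")
  })
  list(auroc_hat_s1 = hat$S1$area, auroc_hat_s2 = hat$S2$area,
       delta_hat = hat$S1$area - hat$S2$area,
       roc_hat_s1 = hat$S1, roc_hat_s2 = hat$S2)
}

#' Metacognitive asymmetry beyond the equal-variance SDT expectation
#'
#' Participant-level summary statistic for the response-bias control
#' hypothesis: the empirical ROC-area asymmetry minus the asymmetry the
#' matched equal-variance SDT observer would produce. Positive values
#' indicate asymmetry that response bias alone cannot explain.
#'
#' @inheritParams matched_delta_auc
#' @return A single number, `delta_auc - delta_hat`.
#' @export
asymmetry_beyond_sdt <- function(trials, fit = NULL) {
  delta_auc(trials)$delta - matched_delta_auc(trials, fit)$delta_hat
}
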