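#' One-tailed one-sample t-test on participant-level differences
#'
#' Tests the group-level directional hypothesis that the mean of the
#' participant-level difference scores exceeds (or falls below) zero, and
#' returns Cohen's d for a one-sample design (`mean / sd`).
#'
#' @param values Numeric vector of per-participant difference scores
#'   (length >= 3, non-degenerate).
#' @param direction `"greater"` if the alternative predicts positive
#'   differences, `"less"` for negative.
#' @return A list with `t`, `p_one_tailed`, `cohens_d`, `n`, `mean_diff`.
#' @examples
#' one_tailed_t(c(0.1, 0.3, 0.2, 0.25), "greater")
#' @export
one_tailed_t <- function(values, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("zero variance in the difference scores")
  tt <- stats::t.test(values, mu = 0, alternative = direction)
  list(t = unname(tt$statistic),
       p_one_tailed = tt$p.value,
       cohens_d = mean(values) / stats::sd(values),
       n = length(values),
       mean_diff = mean(values))
}

#' Jeffreys-Zellner-Siow Bayes factor for a one-sample t statistic
#'
#' BF10 for the one-sample (or paired) t-test under a Cauchy prior on the
#' standardized effect size delta: the marginal likelihood of the observed
#' t statistic — the noncentral t density with noncentrality `delta *
#' sqrt(n)` integrated against `Cauchy(0, rscale)` — divided by the central
#' t density at the null. With `alternative = "directional"` the prior is
#' the positive half-Cauchy, matching a one-tailed hypothesis (pass `-t`
#' for alternatives predicting negative effects).
#'
#' The integral is evaluated by adaptive quadrature after the substitution
#' `delta = rscale * tan(theta)`, which maps the real line to a bounded
#' interval and turns the Cauchy weight into a constant; the integrand is
#' rescaled by its maximum on a probe grid so that extreme t statistics do
#' not overflow. Relative tolerance is 1e-6.
#'
#' @param t Observed t statistic.
#' @param n Sample size (number of difference scores), >= 2.
#' @param rscale Cauchy prior scale on the standardized effect (default
#'   0.65).
#' @param alternative `"two_sided"` (full Cauchy) or `"directional"`
#'   (positive half-Cauchy).
#' @param log Return the natural log of BF10 (robust when BF10 overflows).
#' @return BF10 (or its log), a single number.
#' @examples
#' jzs_bf(2.5, 106)                 # two-sided
#' jzs_bf(2.5, 106, alternative = "directional")
#' @export
jzs_bf <- function(t, n, rscale = 0.65,
                   alternative = c("two_sided", "directional"),
                   log = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(length(t) == 1L, is.finite(t), n >= 2, rscale > 0)
  df <- n - 1
  log_ratio <- function(delta)
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n), log = TRUE) -
                       stats::dt(t, df, log = TRUE))
  lo <- if (alternative == "two_sided") -pi / 2 else 0
  weight <- if (alternative == "two_sided") 1 / pi else 2 / pi
  ## probe the integrand's peak so extreme t cannot overflow the quadrature
  probe <- seq(lo + 1e-6, pi / 2 - 1e-6, length.out = 257L)
  m <- max(log_ratio(rscale * tan(probe)))
  f <- function(theta) exp(log_ratio(rscale * tan(theta)) - m) * weight
  q <- tryCatch(
    stats::integrate(f, lo, pi / 2, rel.tol = 1e-6, subdivisions = 400L),
    error = function(e) stop("JZS quadrature failed (t = ", t, ", n = ", n,
                             "): ", conditionMessage(e)))
  lbf <- m + base::log(q$value)
  if (log) lbf else exp(lbf)
}

#' Group-level confirmatory hypothesis battery
#'
#' Tests the four pre-registered directional hypotheses on the
#' participant-summary table:
#' \describe{
#'   \item{H1 (metacognitive bias)}{mean confidence is higher for S1 than
#'     for S2 responses (`mean_conf_s1 - mean_conf_s2 > 0`).}
#'   \item{H2 (metacognitive asymmetry)}{the type-2 ROC area is higher for
#'     S1 responses (`delta_auc > 0`).}
#'   \item{H3 (asymmetry beyond SDT)}{the asymmetry exceeds the matched
#'     equal-variance SDT expectation (`asymmetry_beyond_sdt > 0`).}
#'   \item{H4 (response time)}{S1 responses are faster
#'     (`mean_log_rt_s1 - mean_log_rt_s2 < 0`).}
#' }
#' Each hypothesis gets a one-tailed t-test at alpha = 0.05 and a JZS Bayes
#' factor; for `bf_sided = "directional"` the half-Cauchy prior is oriented
#' along the alternative (the t statistic is negated for H4 before the BF).
#'
#' @param summaries Participant-summary `data.frame` from
#'   [participant_summaries()] (>= 3 rows).
#' @param rscale Cauchy prior scale (default 0.65).
#' @param bf_sided `"directional"` or `"two_sided"` Bayes factors.
#' @return A `data.frame` of class `"hypothesis_tests"` with one row per
#'   hypothesis: `hypothesis`, `label`, `direction`, `n`, `mean_diff`, `t`,
#'   `p_one_tailed`, `cohens_d`, `bf10`, `bf01`. The prior specification is
#'   attached as attributes `rscale` and `bf_sided`.
#' @export
hypothesis_battery <- function(summaries, rscale = 0.65,
                               bf_sided = c("directional", "two_sided")) {
  bf_sided <- match.arg(bf_sided)
  .check_columns(summaries, c("mean_conf_s1", "mean_conf_s2", "delta_auc",
                              "asymmetry_beyond_sdt", "mean_log_rt_s1",
                              "mean_log_rt_s2"))
  if (nrow(summaries) < 3L) stop("need at least 3 included participants")
  spec <- list(
    H1 = list(label = "confidence (S1 - S2 responses)",
              values = summaries$mean_conf_s1 - summaries$mean_conf_s2,
              direction = "greater"),
    H2 = list(label = "type-2 ROC area asymmetry (dAUC)",
              values = summaries$delta_auc,
              direction = "greater"),
    H3 = list(label = "asymmetry beyond equal-variance SDT",
              values = summaries$asymmetry_beyond_sdt,
              direction = "greater"),
    H4 = list(label = "log response time (S1 - S2 responses)",
              values = summaries$mean_log_rt_s1 - summaries$mean_log_rt_s2,
              direction = "less"))
  rows <- lapply(names(spec), function(h) {
    s <- spec[[h]]
    tt <- one_tailed_t(s$values, s$direction)
    t_for_bf <- if (bf_sided == "directional" && s$direction == "less")
      -tt$t else tt$t
    bf10 <- jzs_bf(t_for_bf, tt$n, rscale = rscale,
                   alternative = if (bf_sided == "directional")
                     "directional" else "two_sided")
    data.frame(hypothesis = h, label = s$label, direction = s$direction,
               n = tt$n, mean_diff = tt$mean_diff, t = tt$t,
               p_one_tailed = tt$p_one_tailed, cohens_d = tt$cohens_d,
               bf10 = bf10, bf01 = 1 / bf10, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rscale") <- rscale
  attr(out, "bf_sided") <- bf_sided
  class(out) <- c("hypothesis_tests", "data.frame")
  out
}

#' @export
print.hypothesis_tests <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Group-level one-tailed t-tests with JZS Bayes factors (rscale = %.2f, %s prior)\n\n",
    attr(x, "rscale"), attr(x, "bf_sided")))
  df <- as.data.frame(x)
  df$mean_diff <- signif(df$mean_diff, digits)
  df$t <- round(df$t, 2)
  df$p_one_tailed <- signif(df$p_one_tailed, digits)
  df$cohens_d <- round(df$cohens_d, 2)
  df$bf10 <- signif(df$bf10, digits)
  df$bf01 <- signif(df$bf01, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
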