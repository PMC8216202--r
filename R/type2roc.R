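#' Response-conditional type-2 ROC curve
#'
#' Builds the empirical type-2 ROC for one response class: the cumulative
#' proportion of incorrect trials at or above each confidence threshold
#' (x axis) against the same cumulative proportion for correct trials
#' (y axis), sweeping thresholds from high to low over the distinct observed
#' confidence values. Tied observations move together, so with the
#' trapezoidal rule the area under the curve equals the tie-corrected
#' Mann-Whitney statistic; it measures how well confidence discriminates
#' correct from incorrect decisions (metacognitive sensitivity).
#'
#' @param conf_correct Confidence ratings on correct trials (>= 1 value).
#' @param conf_incorrect Confidence ratings on incorrect trials (>= 2
#'   values, per the rejection criteria applied upstream).
#' @param response Optional `"S1"`/`"S2"` label stored on the curve.
#' @return An object of class `"roc2"`: a list with `far` and `hr`
#'   (cumulative proportions anchored at (0,0) and (1,1)), `area`,
#'   `response`, `n_correct` and `n_incorrect`.
#' @examples
#' response_conditional_roc(c(0.9, 0.7, 0.6), c(0.5, 0.4))$area  # 1
#' @export
response_conditional_roc <- function(conf_correct, conf_incorrect,
                                     response = NA_character_) {
  conf_correct <- as.numeric(conf_correct)
  conf_incorrect <- as.numeric(conf_incorrect)
  if (anyNA(conf_correct) || anyNA(conf_incorrect))
    stop("confidence ratings must not contain NA")
  if (length(conf_correct) < 1L)
    stop("no correct trials for this response; participant should have ",
         "been excluded upstream")
  if (length(conf_incorrect) < 2L)
    stop("fewer than 2 incorrect trials for this response; participant ",
         "should have been excluded upstream (at least two errors of each ",
         "error type are required)")
  ## descending threshold sweep over the distinct observed values; counts
  ## of ratings >= each threshold via exact value matching (ties move
  ## together), cumulated from the top
  thr <- sort(unique(c(conf_correct, conf_incorrect)), decreasing = TRUE)
  k <- length(thr)
  far <- c(0, cumsum(tabulate(match(conf_incorrect, thr), nbins = k)) /
             length(conf_incorrect))
  hr <- c(0, cumsum(tabulate(match(conf_correct, thr), nbins = k)) /
            length(conf_correct))
  area <- trapezoid_area(far, hr)
  structure(list(far = far, hr = hr, area = area, response = response,
                 n_correct = length(conf_correct),
                 n_incorrect = length(conf_incorrect)),
            class = "roc2")
}

## Trapezoidal rule over a polyline (x non-decreasing).
trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc2 <- function(x, ...) {
  cat("Response-conditional type-2 ROC",
      if (!is.na(x$response)) sprintf("(%s responses)", x$response), "\n")
  cat(sprintf("  %d correct, %d incorrect trials; auROC = %.4f\n",
              x$n_correct, x$n_incorrect, x$area))
  invisible(x)
}

#' @export
plot.roc2 <- function(x, add = FALSE, ...) {
  if (!add) {
    graphics::plot(x$far, x$hr, type = "n", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "P(confidence >= t | incorrect)",
                   ylab = "P(confidence >= t | correct)", asp = 1)
    graphics::abline(0, 1, col = "grey70", lty = 3)
  }
  graphics::lines(x$far, x$hr, type = "o", pch = 16, cex = 0.5, ...)
  invisible(x)
}

#' Brute-force Mann-Whitney area
#'
#' Independent reference for the type-2 ROC area: the proportion of all
#' (correct, incorrect) confidence pairs in which the correct trial has the
#' higher confidence, counting ties as one half. Quadratic in the input
#' sizes; intended for validation, not production use.
#'
#' @inheritParams response_conditional_roc
#' @return The Mann-Whitney area in \[0, 1\].
#' @export
auroc_mwu <- function(conf_correct, conf_incorrect) {
  if (length(conf_correct) < 1L || length(conf_incorrect) < 1L)
    stop("both classes must be non-empty")
  cmp <- outer(conf_correct, conf_incorrect, ">") +
    0.5 * outer(conf_correct, conf_incorrect, "==")
  mean(cmp)
}

#' Metacognitive asymmetry of one participant
#'
#' Area under the type-2 ROC for S1 responses minus the area for S2
#' responses, the participant-level measure of metacognitive asymmetry.
#'
#' @param trials A trial `data.frame` for a single participant with columns
#'   `response`, `correct`, `confidence` (already filtered).
#' @return A list with `auroc_s1`, `auroc_s2`, `delta` and the two
#'   `"roc2"` curves (`roc_s1`, `roc_s2`).
#' @export
delta_auc <- function(trials) {
  .check_columns(trials, c("response", "correct", "confidence"))
  curves <- lapply(c(S1 = "S1", S2 = "S2"), function(r) {
    sub <- trials[trials$response == r, ]
    response_conditional_roc(sub$confidence[sub$correct],
                             sub$confidence[!sub$correct],
                             response = r)
  })
  list(auroc_s1 = curves$S1$area, auroc_s2 = curves$S2$area,
       delta = curves$S1$area - curves$S2$area,
       roc_s1 = curves$S1, roc_s2 = curves$S2)
}

#' Bin confidence ratings over a participant's dynamic range
#'
#' Twenty equal-width bins spanning the participant's own minimum-to-maximum
#' confidence range, for visualisation only — ROC areas are always computed
#' from the unbinned ratings.
#'
#' @param confidences Non-empty numeric vector of ratings.
#' @param n_bins Number of bins (default 20).
#' @return A list with `edges` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`, summing to `length(confidences)`).
#' @export
bin_confidence <- function(confidences, n_bins = 20L) {
  if (length(confidences) == 0L) stop("'confidences' must be non-empty")
  lo <- min(confidences); hi <- max(confidences)
  if (lo == hi) {
    warning("all ratings identical; returning a single degenerate bin")
    return(list(edges = c(lo, hi), counts = length(confidences)))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- graphics::hist(confidences, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  list(edges = edges, counts = counts)
}

.check_columns <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
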