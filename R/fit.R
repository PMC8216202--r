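#' Fit the metacognitive-asymmetry analysis to a trial table
#'
#' The package's main entry point. Takes a trial-level table (or a path to
#' the trial CSV), applies the pre-registered trial and participant
#' rejection criteria, computes per-participant summary variables — mean
#' confidence per response, response-conditional type-2 ROC areas and their
#' difference, the equal-variance-SDT-matched expectation of that
#' difference, and mean log response time per response — and tests the four
#' group-level directional hypotheses with one-tailed t-tests and JZS
#' Bayes factors (see [hypothesis_battery()]).
#'
#' @param trials A trial `data.frame` (see [simulate_cohort()] for the
#'   layout) or a path passed to [read_trials_csv()].
#' @param rscale Cauchy prior scale for the Bayes factors (default 0.65).
#' @param bf_sided `"directional"` (half-Cauchy along each alternative) or
#'   `"two_sided"`.
#' @param rt_floor_ms,rt_ceiling_ms Valid response-time window (ms).
#' @return An object of class `"metacog_asym"` with components `tests`
#'   (the `"hypothesis_tests"` table), `summaries`, `exclusions`, `trials`
#'   (analysed trials of included participants), `n_total`, `n_included`,
#'   and `call`. Methods: [print()], [summary()], [coef()] (group mean
#'   difference per hypothesis), [plot()] (group-averaged ROC curves).
#' @examples
#' trials <- simulate_cohort(12, seed = 42)
#' fit <- metacog_asym(trials)
#' fit
#' coef(fit)
#' @export
metacog_asym <- function(trials, rscale = 0.65,
                         bf_sided = c("directional", "two_sided"),
                         rt_floor_ms = 250, rt_ceiling_ms = 5000) {
  bf_sided <- match.arg(bf_sided)
  if (is.character(trials)) trials <- read_trials_csv(trials)
  if (!"correct" %in% names(trials))
    trials$correct <- trials$stimulus == trials$response
  prep <- participant_summaries(trials, rt_floor_ms, rt_ceiling_ms)
  if (is.null(prep$summaries) || nrow(prep$summaries) < 3L)
    stop("fewer than 3 included participants; see the exclusion report (",
         sum(prep$exclusions$excluded), " of ", nrow(prep$exclusions),
         " excluded: ",
         paste(unique(prep$exclusions$reasons[prep$exclusions$excluded]),
               collapse = ", "), ")")
  tests <- hypothesis_battery(prep$summaries, rscale = rscale,
                              bf_sided = bf_sided)
  structure(list(tests = tests, summaries = prep$summaries,
                 exclusions = prep$exclusions, trials = prep$trials,
                 n_total = nrow(prep$exclusions),
                 n_included = nrow(prep$summaries),
                 rscale = rscale, bf_sided = bf_sided,
                 call = match.call()),
            class = "metacog_asym")
}

#' @export
print.metacog_asym <- function(x, ...) {
  cat("Metacognitive asymmetry analysis\n")
  cat(sprintf("  %d participants (%d included, %d excluded)\n",
              x$n_total, x$n_included, x$n_total - x$n_included))
  print(x$tests)
  invisible(x)
}

#' @export
summary.metacog_asym <- function(object, ...) {
  structure(list(fit = object), class = "summary.metacog_asym")
}

#' @export
print.summary.metacog_asym <- function(x, ...) {
  f <- x$fit
  print(f)
  excl <- f$exclusions[f$exclusions$excluded, , drop = FALSE]
  if (nrow(excl)) {
    cat("\nExclusions:\n")
    print.data.frame(excl[, c("participant_id", "reasons", "accuracy")],
                     row.names = FALSE)
  }
  cat(sprintf("\nGroup means: auROC(S1) = %.3f, auROC(S2) = %.3f, dAUC = %.3f (SDT-matched %.3f)\n",
              mean(f$summaries$auroc_s1), mean(f$summaries$auroc_s2),
              mean(f$summaries$delta_auc),
              mean(f$summaries$matched_delta_auc)))
  invisible(x)
}

#' @export
coef.metacog_asym <- function(object, ...) {
  stats::setNames(object$tests$mean_diff, object$tests$hypothesis)
}

#' Group-averaged response-conditional ROC curves
#'
#' Averages each participant's empirical and SDT-matched model curves on a
#' common false-alarm-rate grid (linear interpolation between curve
#' vertices) and plots both responses: solid for the empirical curves,
#' dashed for the matched equal-variance model.
#'
#' @param x A `"metacog_asym"` fit.
#' @param grid_n Number of interpolation points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.metacog_asym <- function(x, grid_n = 101L, ...) {
  grid <- seq(0, 1, length.out = grid_n)
  avg_curve <- function(kind, resp) {
    per <- lapply(split(x$trials, x$trials$participant_id), function(tr) {
      cv <- if (kind == "empirical") {
        e <- delta_auc(tr); if (resp == "S1") e$roc_s1 else e$roc_s2
      } else {
        h <- matched_delta_auc(tr)
        if (resp == "S1") h$roc_hat_s1 else h$roc_hat_s2
      }
      stats::approx(cv$far, cv$hr, xout = grid, ties = max)$y
    })
    rowMeans(do.call(cbind, per))
  }
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), asp = 1,
                 xlab = "cumulative P(conf >= t | incorrect)",
                 ylab = "cumulative P(conf >= t | correct)",
                 main = "Response-conditional type-2 ROC", ...)
  graphics::abline(0, 1, col = "grey70", lty = 3)
  cols <- c(S1 = "#1b61a8", S2 = "#c23b22")
  for (resp in c("S1", "S2")) {
    graphics::lines(grid, avg_curve("empirical", resp), col = cols[resp],
                    lwd = 2)
    graphics::lines(grid, avg_curve("model", resp), col = cols[resp],
                    lwd = 1.5, lty = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = c(2, 2, 1.5),
                   lty = c(1, 1, 2),
                   col = c(cols, "grey30"),
                   legend = c("S1 responses", "S2 responses",
                              "matched SDT model"))
  invisible(x)
}
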