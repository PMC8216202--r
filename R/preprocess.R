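#' Apply the pre-registered trial rejection rules
#'
#' Drops first-block trials (only the last five blocks are analysed) and
#' trials with response times outside the valid window (below 250 ms or
#' above 5 s by default). Row order is preserved and the input is not
#' modified; the operation is idempotent.
#'
#' @param trials Trial `data.frame` with columns `block` and `rt_ms`.
#' @param rt_floor_ms,rt_ceiling_ms Valid response-time window (ms).
#' @param drop_block Block index to drop (the practice-adjacent first
#'   block).
#' @return The filtered `data.frame`.
#' @export
filter_trials <- function(trials, rt_floor_ms = 250, rt_ceiling_ms = 5000,
                          drop_block = 1L) {
  .check_columns(trials, c("block", "rt_ms"))
  keep <- trials$block != drop_block &
    trials$rt_ms >= rt_floor_ms & trials$rt_ms <= rt_ceiling_ms
  trials[keep, , drop = FALSE]
}

#' Participant-level rejection rules
#'
#' Applies the pre-registered participant exclusion criteria to one
#' participant. Accuracy and error-count rules are evaluated on the
#' analysed trials (after [filter_trials()]), since those are the trials
#' that feed the ROC analysis; the response-time proportion rule is
#' evaluated on all trials, as registered. A participant is excluded when:
#' accuracy is below 60%; more than 25% of all trials have response times
#' outside \[250 ms, 5 s\]; the comprehension check was failed; or either
#' response type has fewer than two errors (type-2 ROC curves require
#' incorrect responses of both kinds).
#'
#' @param trials All of one participant's trials (unfiltered).
#' @param comprehension_pass Logical; did the participant pass the
#'   comprehension check? Defaults to the `comprehension_pass` column when
#'   present, else `TRUE`.
#' @param rt_floor_ms,rt_ceiling_ms Valid response-time window (ms).
#' @return A one-row `data.frame` (an exclusion report): `participant_id`,
#'   `excluded`, `reasons` (semicolon-separated, `""` when included),
#'   `accuracy`, `prop_rt_out_of_range`, `n_errors_s1_response`,
#'   `n_errors_s2_response`.
#' @export
participant_exclusion <- function(trials, comprehension_pass = NULL,
                                  rt_floor_ms = 250, rt_ceiling_ms = 5000) {
  .check_columns(trials, c("block", "rt_ms", "response", "correct"))
  if (nrow(trials) == 0L) stop("empty trial set")
  if (is.null(comprehension_pass)) {
    comprehension_pass <- if ("comprehension_pass" %in% names(trials))
      all(trials$comprehension_pass) else TRUE
  }
  analysed <- filter_trials(trials, rt_floor_ms, rt_ceiling_ms)
  accuracy <- if (nrow(analysed)) mean(analysed$correct) else NA_real_
  prop_out <- mean(trials$rt_ms < rt_floor_ms | trials$rt_ms > rt_ceiling_ms)
  n_err_s1 <- sum(analysed$response == "S1" & !analysed$correct)
  n_err_s2 <- sum(analysed$response == "S2" & !analysed$correct)
  reasons <- character(0)
  if (is.na(accuracy) || accuracy < 0.60) reasons <- c(reasons, "low_accuracy")
  if (prop_out > 0.25) reasons <- c(reasons, "rt_violations")
  if (!isTRUE(comprehension_pass)) reasons <- c(reasons, "comprehension_fail")
  if (n_err_s1 < 2L || n_err_s2 < 2L) reasons <- c(reasons, "too_few_errors")
  pid <- if ("participant_id" %in% names(trials))
    trials$participant_id[1] else NA_character_
  data.frame(participant_id = pid,
             excluded = length(reasons) > 0L,
             reasons = paste(reasons, collapse = ";"),
             accuracy = accuracy,
             prop_rt_out_of_range = prop_out,
             n_errors_s1_response = n_err_s1,
             n_errors_s2_response = n_err_s2,
             stringsAsFactors = FALSE)
}

#' Exclusion report for a whole cohort
#'
#' @param trials Trial `data.frame` for several participants (unfiltered),
#'   with a `participant_id` column and optionally `comprehension_pass`.
#' @inheritParams participant_exclusion
#' @return A `data.frame` with one exclusion report row per participant.
#' @export
exclusion_report <- function(trials, rt_floor_ms = 250,
                             rt_ceiling_ms = 5000) {
  .check_columns(trials, "participant_id")
  parts <- split(trials, trials$participant_id)
  out <- do.call(rbind, lapply(parts, participant_exclusion,
                               rt_floor_ms = rt_floor_ms,
                               rt_ceiling_ms = rt_ceiling_ms))
  rownames(out) <- NULL
  out
}

#' Per-participant summary variables
#'
#' Computes the four hypothesis-level dependent variables for one included
#' participant from their analysed (filtered) trials: mean confidence per
#' response, response-conditional type-2 ROC areas and their difference,
#' the SDT-matched expected difference and the asymmetry beyond it, and
#' mean natural-log response time per response.
#'
#' @param trials One participant's filtered trials (see [filter_trials()]).
#' @return A one-row `data.frame` with columns `participant_id`,
#'   `mean_conf_s1`, `mean_conf_s2`, `auroc_s1`, `auroc_s2`, `delta_auc`,
#'   `auroc_hat_s1`, `auroc_hat_s2`, `matched_delta_auc`,
#'   `asymmetry_beyond_sdt`, `mean_log_rt_s1`, `mean_log_rt_s2`.
#' @export
summarize_participant <- function(trials) {
  .check_columns(trials, c("stimulus", "response", "correct", "confidence",
                           "rt_ms"))
  is_s1 <- trials$response == "S1"
  emp <- delta_auc(trials)
  fit <- estimate_sdt(trials)
  hat <- matched_delta_auc(trials, fit)
  pid <- if ("participant_id" %in% names(trials))
    trials$participant_id[1] else NA_character_
  data.frame(participant_id = pid,
             mean_conf_s1 = mean(trials$confidence[is_s1]),
             mean_conf_s2 = mean(trials$confidence[!is_s1]),
             auroc_s1 = emp$auroc_s1, auroc_s2 = emp$auroc_s2,
             delta_auc = emp$delta,
             auroc_hat_s1 = hat$auroc_hat_s1,
             auroc_hat_s2 = hat$auroc_hat_s2,
             matched_delta_auc = hat$delta_hat,
             asymmetry_beyond_sdt = emp$delta - hat$delta_hat,
             mean_log_rt_s1 = mean(log(trials$rt_ms[is_s1])),
             mean_log_rt_s2 = mean(log(trials$rt_ms[!is_s1])),
             stringsAsFactors = FALSE)
}

#' Summaries for all included participants
#'
#' Runs the full preprocessing chain on a cohort: trial filtering,
#' participant exclusion, and per-participant summaries for the survivors.
#'
#' @param trials Cohort trial `data.frame` (unfiltered).
#' @inheritParams participant_exclusion
#' @return A list with `summaries` (one row per included participant),
#'   `exclusions` (the full [exclusion_report()]) and `trials` (the
#'   filtered trials of included participants).
#' @export
participant_summaries <- function(trials, rt_floor_ms = 250,
                                  rt_ceiling_ms = 5000) {
  excl <- exclusion_report(trials, rt_floor_ms, rt_ceiling_ms)
  keep_ids <- excl$participant_id[!excl$excluded]
  kept <- trials[trials$participant_id %in% keep_ids, , drop = FALSE]
  kept <- filter_trials(kept, rt_floor_ms, rt_ceiling_ms)
  summaries <- do.call(rbind, lapply(split(kept, kept$participant_id),
                                     summarize_participant))
  rownames(summaries) <- NULL
  list(summaries = summaries, exclusions = excl, trials = kept)
}
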