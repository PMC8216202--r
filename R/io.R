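#' Read a trial-level CSV
#'
#' Reads and validates the interchange format: comma-delimited, UTF-8, one
#' row per trial with columns `participant_id`, `block`, `trial`,
#' `stimulus`, `response`, `confidence`, `rt_ms`, `soa_ms`,
#' `comprehension_pass`. Stimulus and response values must be `"S1"` or
#' `"S2"`; confidence must lie in \[0, 1\] and response times must be
#' positive. Malformed rows are dropped with a warning when they make up at
#' most 1% of the file, and are fatal above that.
#'
#' @param path Path to the CSV file.
#' @return A validated trial `data.frame`.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "block", "trial", "stimulus", "response",
                "confidence", "rt_ms", "soa_ms", "comprehension_pass")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$comprehension_pass <- as.logical(df$comprehension_pass)
  bad <- !(df$stimulus %in% c("S1", "S2")) |
    !(df$response %in% c("S1", "S2")) |
    is.na(df$confidence) | df$confidence < 0 | df$confidence > 1 |
    is.na(df$rt_ms) | df$rt_ms <= 0 |
    is.na(df$comprehension_pass)
  if (any(bad)) {
    if (mean(bad) > 0.01)
      stop(sum(bad), " malformed rows (", round(100 * mean(bad), 1),
           "% of the file) in ", path)
    warning(sum(bad), " malformed row(s) dropped from ", path)
    df <- df[!bad, , drop = FALSE]
  }
  df$correct <- df$stimulus == df$response
  rownames(df) <- NULL
  df
}

#' Write a trial-level CSV
#'
#' @param trials Trial `data.frame` (e.g. from [simulate_cohort()]).
#' @param path Output path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE to replace it")
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Tidy export of a participant's ROC curves
#'
#' @param trials One participant's filtered trials.
#' @return A long `data.frame` with columns `participant_id`, `response`,
#'   `kind` (`"empirical"`/`"model"`), `far`, `hr` — the empirical type-2
#'   ROC and the matched equal-variance SDT curve for both responses.
#' @export
roc_curves_table <- function(trials) {
  emp <- delta_auc(trials)
  hat <- matched_delta_auc(trials)
  pid <- if ("participant_id" %in% names(trials))
    trials$participant_id[1] else NA_character_
  one <- function(curve, kind)
    data.frame(participant_id = pid, response = curve$response, kind = kind,
               far = curve$far, hr = curve$hr, stringsAsFactors = FALSE)
  rbind(one(emp$roc_s1, "empirical"), one(emp$roc_s2, "empirical"),
        one(hat$roc_hat_s1, "model"), one(hat$roc_hat_s2, "model"))
}

#' Run the full analysis pipeline on a trial table
#'
#' Filter trials, apply participant exclusions, compute participant
#' summaries and run the hypothesis battery; write all artifacts
#' (`exclusions.csv`, `summaries.csv`, `roc_curves.csv`, `report.json`,
#' `run.log`) to `output_dir`.
#'
#' @param input Path to a trial CSV or a trial `data.frame`.
#' @param output_dir Directory for the artifacts (created if needed).
#' @param seed Optional integer recorded in the outputs (the analysis
#'   itself is deterministic).
#' @param rscale,bf_sided Passed to [hypothesis_battery()].
#' @param overwrite Allow replacing existing artifacts.
#' @return The fitted [metacog_asym()] object, invisibly.
#' @export
run_pipeline <- function(input, output_dir, seed = NULL, rscale = 0.65,
                         bf_sided = c("directional", "two_sided"),
                         overwrite = FALSE) {
  bf_sided <- match.arg(bf_sided)
  trials <- if (is.character(input)) read_trials_csv(input) else input
  fit <- metacog_asym(trials, rscale = rscale, bf_sided = bf_sided)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) {
    p <- file.path(output_dir, name)
    if (file.exists(p) && !overwrite)
      stop("'", p, "' exists; use overwrite = TRUE to replace it")
    p
  }
  utils::write.csv(fit$exclusions, outfile("exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$summaries, outfile("summaries.csv"),
                   row.names = FALSE)
  roc <- do.call(rbind, lapply(split(fit$trials, fit$trials$participant_id),
                               roc_curves_table))
  rownames(roc) <- NULL
  utils::write.csv(roc, outfile("roc_curves.csv"), row.names = FALSE)
  report <- list(seed = seed,
                 prior = list(rscale = rscale, bf_sided = bf_sided),
                 n_participants_total = nrow(fit$exclusions),
                 n_included = nrow(fit$summaries),
                 exclusion_reasons = table(
                   fit$exclusions$reasons[fit$exclusions$excluded]),
                 hypotheses = as.data.frame(fit$tests))
  jsonlite::write_json(report, outfile("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  log_lines <- c(
    sprintf("metasym %s | %s", as.character(utils::packageVersion("metasym")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("prior: JZS Cauchy rscale %.3f, %s", rscale, bf_sided),
    sprintf("rows in: %d", nrow(trials)),
    sprintf("rows analysed (post filter, included participants): %d",
            nrow(fit$trials)),
    sprintf("participants: %d total, %d included, %d excluded",
            nrow(fit$exclusions), nrow(fit$summaries),
            sum(fit$exclusions$excluded)))
  writeLines(log_lines, outfile("run.log"))
  invisible(fit)
}
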