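## 12-trial toy participant used for hand-checked summaries.
## Layout: 6 S1 responses (4 correct, 2 errors), 6 S2 responses
## (4 correct, 2 errors); RTs 500..1600 ms in row order.
toy_trials <- function() {
  data.frame(
    participant_id = "P001", block = 2L, trial = 1:12,
    stimulus = c("S1", "S1", "S1", "S1", "S2", "S2",
                 "S2", "S2", "S2", "S2", "S1", "S1"),
    response = c("S1", "S1", "S1", "S1", "S1", "S1",
                 "S2", "S2", "S2", "S2", "S2", "S2"),
    confidence = c(0.9, 0.7, 0.6, 0.8, 0.5, 0.4,
                   0.85, 0.55, 0.45, 0.65, 0.35, 0.6),
    rt_ms = seq(500, 1600, by = 100),
    soa_ms = 20, comprehension_pass = TRUE,
    stringsAsFactors = FALSE)
}

with_correct <- function(df) { df$correct <- df$stimulus == df$response; df }

## Brute-force pairwise AUC written independently of the package internals.
brute_auc <- function(cc, ci) {
  tot <- 0
  for (a in cc) for (b in ci) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cc) * length(ci))
}

## Construct an sdt_fit without going through estimate_sdt().
make_fit <- function(dprime, criterion_c) {
  structure(list(dprime = dprime, criterion_c = criterion_c,
                 hr = NA, far = NA, n_s1 = NA, n_s2 = NA),
            class = "sdt_fit")
}

## A stationary cohort of equal- or unequal-variance SDT observers with
## noise-free confidence, for control-validity checks.
stationary_cohort <- function(n_participants, n_trials, dprime, sigma_s1,
                              criterion, seed) {
  set.seed(seed)
  obs <- observer_params(sigma_s1 = sigma_s1, criterion_c = criterion,
                         conf_noise_sd = 0, lapse_rate = 0)
  do.call(rbind, lapply(seq_len(n_participants), function(i)
    simulate_stationary(n_trials, dprime, obs,
                        participant_id = sprintf("P%03d", i))))
}
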