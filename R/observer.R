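#' Experiment configuration
#'
#' Settings of the masked discrimination task: trial counts, block structure,
#' the staircase starting point and step, and the response-time window used
#' downstream by the trial rejection rules.
#'
#' @param experiment_label Name of the stimulus pair (e.g. `"Q_in_O"`); a
#'   label only, it does not change the simulation.
#' @param n_trials Trials per participant; must be divisible by `n_blocks`.
#' @param n_blocks Number of blocks. The first block is dropped at analysis.
#' @param soa_start_ms Staircase starting stimulus onset asynchrony (ms).
#' @param step_factor Multiplicative staircase step, strictly in (0, 1).
#' @param rt_floor_ms,rt_ceiling_ms Valid response-time window (ms) used by
#'   [filter_trials()] and the participant rejection rules.
#'
#' @return An object of class `"experiment_config"` (a named list).
#' @examples
#' experiment_config()
#' @export
experiment_config <- function(experiment_label = "Q_in_O",
                              n_trials = 96L,
                              n_blocks = 6L,
                              soa_start_ms = 30,
                              step_factor = 0.9,
                              rt_floor_ms = 250,
                              rt_ceiling_ms = 5000) {
  n_trials <- as.integer(n_trials)
  n_blocks <- as.integer(n_blocks)
  if (n_trials < 1L || n_blocks < 1L || n_trials %% n_blocks != 0L)
    stop("'n_trials' must be a positive multiple of 'n_blocks'")
  if (!(step_factor > 0 && step_factor < 1))
    stop("'step_factor' must lie strictly between 0 and 1")
  if (soa_start_ms <= 0) stop("'soa_start_ms' must be positive")
  if (rt_floor_ms <= 0 || rt_ceiling_ms <= rt_floor_ms)
    stop("invalid response-time window")
  structure(list(experiment_label = experiment_label,
                 n_trials = n_trials, n_blocks = n_blocks,
                 soa_start_ms = soa_start_ms, step_factor = step_factor,
                 rt_floor_ms = rt_floor_ms, rt_ceiling_ms = rt_ceiling_ms),
            class = "experiment_config")
}

#' Observer parameters
#'
#' Generative parameters of a simulated observer. Perceptual evidence on a
#' trial is drawn from `Normal(d', sigma_s1)` when the feature-present
#' stimulus S1 is shown and from `Normal(0, 1)` for the feature-absent S2;
#' the observer responds S1 when evidence exceeds `criterion_c`.
#' `sigma_s1 >= 1` encodes the presence/absence asymmetry: `sigma_s1 = 1`
#' is the equal-variance observer, for which no metacognitive asymmetry is
#' expected beyond what response bias induces.
#'
#' Confidence is a logistic squash of the distance between evidence and
#' criterion, corrupted by metacognitive noise and clipped to \[0, 1\];
#' response time is lognormal with median log-RT decreasing in confidence.
#'
#' @param dprime_max Asymptotic sensitivity at long SOA (d' units).
#' @param soa_half_point_ms SOA (ms) at which sensitivity reaches half of
#'   `dprime_max`.
#' @param sigma_s1 Standard deviation of the S1 evidence distribution
#'   (S2 is fixed at 1); must be >= 1.
#' @param criterion_c Decision criterion on the evidence axis.
#' @param conf_gain Slope of the logistic mapping from distance-to-criterion
#'   to confidence.
#' @param conf_noise_sd SD of Gaussian metacognitive noise added to the
#'   distance-to-criterion before squashing.
#' @param rt_scale_ms Median response time (ms) at mid confidence.
#' @param rt_shape Lognormal shape (sdlog) of response times.
#' @param rt_conf_slope Decrease in log median RT per unit confidence.
#' @param lapse_rate Probability of flipping the response after the evidence
#'   rule (attentional lapse); in \[0, 0.5).
#'
#' @return An object of class `"observer_params"` (a named list).
#' @examples
#' observer_params(sigma_s1 = 1)  # equal-variance observer
#' @export
observer_params <- function(dprime_max = 3,
                            soa_half_point_ms = 25,
                            sigma_s1 = 1.15,
                            criterion_c = 0.55,
                            conf_gain = 1.5,
                            conf_noise_sd = 0.6,
                            rt_scale_ms = 900,
                            rt_shape = 0.35,
                            rt_conf_slope = 0.8,
                            lapse_rate = 0.02) {
  if (dprime_max <= 0) stop("'dprime_max' must be positive")
  if (soa_half_point_ms <= 0) stop("'soa_half_point_ms' must be positive")
  if (sigma_s1 < 1) stop("'sigma_s1' must be >= 1 (S2 sd is fixed at 1)")
  if (conf_noise_sd < 0 || rt_shape <= 0 || rt_scale_ms <= 0 || conf_gain <= 0)
    stop("confidence/RT parameters out of range")
  if (lapse_rate < 0 || lapse_rate >= 0.5)
    stop("'lapse_rate' must be in [0, 0.5)")
  structure(list(dprime_max = dprime_max,
                 soa_half_point_ms = soa_half_point_ms,
                 sigma_s1 = sigma_s1, criterion_c = criterion_c,
                 conf_gain = conf_gain, conf_noise_sd = conf_noise_sd,
                 rt_scale_ms = rt_scale_ms, rt_shape = rt_shape,
                 rt_conf_slope = rt_conf_slope, lapse_rate = lapse_rate),
            class = "observer_params")
}

#' Staircase state
#'
#' @param soa_ms Current stimulus onset asynchrony (ms), positive.
#' @param consecutive_correct Number of consecutive correct responses since
#'   the last step (0 or 1).
#' @return An object of class `"staircase_state"`.
#' @export
staircase_state <- function(soa_ms = 30, consecutive_correct = 0L) {
  if (soa_ms <= 0) stop("'soa_ms' must be positive")
  structure(list(soa_ms = soa_ms,
                 consecutive_correct = as.integer(consecutive_correct)),
            class = "staircase_state")
}

#' One step of the 1-up-2-down staircase
#'
#' After two consecutive correct responses the SOA is multiplied by
#' `step_factor` (the task gets harder) and the counter resets; after any
#' error the SOA is divided by `step_factor` and the counter resets;
#' otherwise only the counter increments. With multiplicative, equal up and
#' down steps this procedure converges on the SOA at which the probability
#' of a correct response is sqrt(1/2), about 70.7%.
#'
#' @param state A [staircase_state()].
#' @param correct Logical, was the response correct?
#' @param step_factor Multiplicative step, in (0, 1).
#' @return The updated `"staircase_state"`.
#' @examples
#' staircase_update(staircase_state(30, 1), TRUE)   # -> 27 ms
#' staircase_update(staircase_state(27, 0), FALSE)  # -> 30 ms
#' @export
staircase_update <- function(state, correct, step_factor = 0.9) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (!correct) {
    state$soa_ms <- state$soa_ms / step_factor
    state$consecutive_correct <- 0L
  } else if (state$consecutive_correct >= 1L) {
    state$soa_ms <- state$soa_ms * step_factor
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
  }
  state
}

#' Sensitivity as a function of SOA
#'
#' Saturating hyperbolic link between stimulus onset asynchrony and
#' discrimination sensitivity:
#' `d'(soa) = dprime_max * soa / (soa + soa_half_point_ms)`. It is zero at
#' zero SOA, monotone increasing, and reaches half its asymptote at the
#' half-point, giving the staircase a smooth psychometric function to act on.
#'
#' @param soa_ms SOA in ms (vectorised); must be non-negative.
#' @param obs An [observer_params()] object.
#' @return Sensitivity d' (same length as `soa_ms`).
#' @export
psychometric_dprime <- function(soa_ms, obs) {
  stopifnot(inherits(obs, "observer_params"))
  if (any(soa_ms < 0)) stop("'soa_ms' must be non-negative")
  obs$dprime_max * soa_ms / (soa_ms + obs$soa_half_point_ms)
}

## Shared evidence -> (response, confidence) core, vectorised over trials.
## stim_s1: logical vector; returns list(response_s1, confidence, dist).
.evidence_core <- function(stim_s1, dprime, obs) {
  n <- length(stim_s1)
  x <- stats::rnorm(n,
                    mean = ifelse(stim_s1, dprime, 0),
                    sd   = ifelse(stim_s1, obs$sigma_s1, 1))
  resp_s1 <- x > obs$criterion_c
  if (obs$lapse_rate > 0) {
    flip <- stats::runif(n) < obs$lapse_rate
    resp_s1 <- xor(resp_s1, flip)
  }
  d <- abs(x - obs$criterion_c)
  if (obs$conf_noise_sd > 0)
    d <- d + stats::rnorm(n, 0, obs$conf_noise_sd)
  conf <- 2 * stats::plogis(obs$conf_gain * d) - 1
  conf <- pmin(1, pmax(0, conf))
  list(response_s1 = resp_s1, confidence = conf)
}

.draw_rt <- function(confidence, obs) {
  mu <- log(obs$rt_scale_ms) - obs$rt_conf_slope * (confidence - 0.5)
  stats::rlnorm(length(confidence), meanlog = mu, sdlog = obs$rt_shape)
}

#' Simulate a single trial
#'
#' Draws the stimulus equiprobably, forms evidence under the observer's
#' unequal-variance model at the sensitivity implied by the current SOA,
#' applies the decision rule (with lapses), and generates confidence and
#' response time. Uses the R random number stream; call [set.seed()] for
#' reproducibility.
#'
#' @param state A [staircase_state()] giving the current SOA.
#' @param obs An [observer_params()] object.
#' @param cfg An [experiment_config()] object.
#' @return A one-row `data.frame` with columns `stimulus`, `response`,
#'   `correct`, `confidence`, `rt_ms`, `soa_ms`.
#' @export
simulate_trial <- function(state, obs, cfg = experiment_config()) {
  stopifnot(inherits(state, "staircase_state"))
  dp <- psychometric_dprime(state$soa_ms, obs)
  stim_s1 <- stats::runif(1) < 0.5
  ev <- .evidence_core(stim_s1, dp, obs)
  data.frame(stimulus  = if (stim_s1) "S1" else "S2",
             response   = if (ev$response_s1) "S1" else "S2",
             correct    = stim_s1 == ev$response_s1,
             confidence = ev$confidence,
             rt_ms      = .draw_rt(ev$confidence, obs),
             soa_ms     = state$soa_ms,
             stringsAsFactors = FALSE)
}

#' Simulate one participant's session
#'
#' Runs `cfg$n_trials` trials with a fresh 1-up-2-down staircase acting
#' between every pair of consecutive trials, including during the first
#' block (analysis drops block 1 downstream).
#'
#' @inheritParams simulate_trial
#' @param participant_id Identifier copied into every row.
#' @return A `data.frame` of trial records with columns `participant_id`,
#'   `block`, `trial`, `stimulus`, `response`, `correct`, `confidence`,
#'   `rt_ms`, `soa_ms`.
#' @export
simulate_participant <- function(participant_id, obs,
                                 cfg = experiment_config()) {
  n <- cfg$n_trials
  per_block <- n %/% cfg$n_blocks
  soa <- numeric(n); stim <- logical(n); resp <- logical(n)
  conf <- numeric(n)
  st <- staircase_state(cfg$soa_start_ms)
  for (i in seq_len(n)) {
    soa[i] <- st$soa_ms
    dp <- psychometric_dprime(st$soa_ms, obs)
    stim[i] <- stats::runif(1) < 0.5
    ev <- .evidence_core(stim[i], dp, obs)
    resp[i] <- ev$response_s1
    conf[i] <- ev$confidence
    st <- staircase_update(st, stim[i] == resp[i], cfg$step_factor)
  }
  data.frame(participant_id = participant_id,
             block      = rep(seq_len(cfg$n_blocks), each = per_block),
             trial      = seq_len(n),
             stimulus   = ifelse(stim, "S1", "S2"),
             response   = ifelse(resp, "S1", "S2"),
             correct    = stim == resp,
             confidence = conf,
             rt_ms      = .draw_rt(conf, obs),
             soa_ms     = soa,
             stringsAsFactors = FALSE)
}

#' Population of observers
#'
#' Between-participant distribution from which [simulate_cohort()] draws
#' each observer's parameters. Gaussian variation around the stated means,
#' with `sigma_s1` truncated below at 1 (the equal-variance bound) and
#' criteria left unconstrained. `comprehension_rate` is the probability of
#' passing the instructions comprehension check.
#'
#' @param sigma_s1_mean,sigma_s1_sd Mean and SD of the S1 evidence SD; set
#'   `sigma_s1_mean = 1, sigma_s1_sd = 0` for an equal-variance population.
#' @param dprime_max_mean,dprime_max_sd Asymptotic sensitivity.
#' @param criterion_mean,criterion_sd Decision criterion.
#' @param conf_noise_mean Metacognitive noise SD (constant across observers).
#' @param comprehension_rate Probability of passing the comprehension check.
#' @param ... Further scalar overrides passed to [observer_params()]
#'   (e.g. `lapse_rate`, `rt_scale_ms`).
#' @return An object of class `"cohort_population"`.
#' @export
cohort_population <- function(sigma_s1_mean = 1.15, sigma_s1_sd = 0.25,
                              dprime_max_mean = 3, dprime_max_sd = 0.4,
                              criterion_mean = 0.55, criterion_sd = 0.15,
                              conf_noise_mean = 0.6,
                              comprehension_rate = 0.98, ...) {
  if (sigma_s1_mean < 1) stop("'sigma_s1_mean' must be >= 1")
  if (comprehension_rate < 0 || comprehension_rate > 1)
    stop("'comprehension_rate' must be a probability")
  structure(list(sigma_s1_mean = sigma_s1_mean, sigma_s1_sd = sigma_s1_sd,
                 dprime_max_mean = dprime_max_mean,
                 dprime_max_sd = dprime_max_sd,
                 criterion_mean = criterion_mean,
                 criterion_sd = criterion_sd,
                 conf_noise_mean = conf_noise_mean,
                 comprehension_rate = comprehension_rate,
                 extra = list(...)),
            class = "cohort_population")
}

.draw_observer <- function(pop) {
  args <- c(list(
    dprime_max = max(0.5, stats::rnorm(1, pop$dprime_max_mean,
                                       pop$dprime_max_sd)),
    sigma_s1 = max(1, stats::rnorm(1, pop$sigma_s1_mean, pop$sigma_s1_sd)),
    criterion_c = stats::rnorm(1, pop$criterion_mean, pop$criterion_sd),
    conf_noise_sd = pop$conf_noise_mean), pop$extra)
  do.call(observer_params, args)
}

#' Simulate a cohort
#'
#' Draws each participant's observer parameters from `population`, simulates
#' a full staircased session per participant, and attaches the
#' comprehension-check flag. One master seed controls everything; each
#' participant gets a sub-stream derived deterministically from it, so the
#' output is bit-reproducible under a fixed seed.
#'
#' @param n_participants Number of participants (>= 1).
#' @param cfg An [experiment_config()].
#' @param population A [cohort_population()].
#' @param seed Optional integer master seed.
#' @return A `data.frame` of trial records (see [simulate_participant()])
#'   with an additional logical `comprehension_pass` column, constant within
#'   participant.
#' @examples
#' trials <- simulate_cohort(3, seed = 1)
#' table(trials$participant_id)
#' @export
simulate_cohort <- function(n_participants,
                            cfg = experiment_config(),
                            population = cohort_population(),
                            seed = NULL) {
  stopifnot(n_participants >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_participants)
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(sub_seeds[i])
    obs <- .draw_observer(population)
    df <- simulate_participant(sprintf("P%03d", i), obs, cfg)
    df$comprehension_pass <- stats::runif(1) < population$comprehension_rate
    out[[i]] <- df
  }
  do.call(rbind, out)
}

#' Simulate a stationary signal-detection observer
#'
#' Generates trials at a fixed sensitivity (no staircase, no block
#' structure), useful for Monte-Carlo checks of the ROC machinery and of the
#' equal-variance control. Block is set to 2 and response times to a valid
#' constant so the output passes [filter_trials()] untouched.
#'
#' @param n_trials Number of trials.
#' @param dprime Fixed sensitivity.
#' @param obs An [observer_params()] object supplying `sigma_s1`,
#'   `criterion_c`, confidence and lapse parameters.
#' @param participant_id Identifier for the output rows.
#' @return A trial `data.frame` in the same layout as
#'   [simulate_participant()].
#' @export
simulate_stationary <- function(n_trials, dprime, obs,
                                participant_id = "P001") {
  stim <- stats::runif(n_trials) < 0.5
  ev <- .evidence_core(stim, dprime, obs)
  data.frame(participant_id = participant_id,
             block = 2L, trial = seq_len(n_trials),
             stimulus = ifelse(stim, "S1", "S2"),
             response = ifelse(ev$response_s1, "S1", "S2"),
             correct = stim == ev$response_s1,
             confidence = ev$confidence,
             rt_ms = 1000, soa_ms = NA_real_,
             stringsAsFactors = FALSE)
}
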