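---
title: "Methods: response-conditional type-2 ROC analysis of metacognitive asymmetry"
author: "metasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metacognitive asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasym)
```

## The scientific question

In near-threshold detection, "yes, it was there" judgments are accompanied
by higher confidence and better metacognitive sensitivity than "no, nothing
there" judgments. This package implements the analysis pipeline of a study
asking whether the same asymmetry appears in *discrimination* between a
feature-present stimulus (S1: a Q among Os, a tilted line, a shaded cube)
and its feature-absent counterpart (S2). On each trial a masked stimulus is
shown briefly, the participant makes a forced-choice discrimination
judgment and rates confidence on a continuous scale. Difficulty is held at
threshold by an adaptive staircase on the stimulus onset asynchrony (SOA)
between stimulus and mask.

Four directional group-level hypotheses are tested, all operating on
per-participant summary statistics:

* **H1 (metacognitive bias).** Mean confidence is higher for S1 than for S2
  responses.
* **H2 (metacognitive sensitivity).** The area under the
  response-conditional type-2 ROC curve (auROC) is higher for S1 responses:
  ΔAUC = auROC(S1) − auROC(S2) > 0.
* **H3 (asymmetry beyond response bias).** ΔAUC exceeds the value expected
  from an equal-variance signal detection observer matched to the
  participant's sensitivity, response bias, and error-confidence
  distribution.
* **H4 (response time).** S1 responses are faster: the difference in mean
  log RT is negative.

## Type-2 ROC curves and their area

For one response class, the type-2 ROC plots, for every confidence
threshold `t` (swept from high to low over the distinct observed values),
the cumulative proportion of *incorrect* trials with confidence ≥ t against
the same proportion for *correct* trials. `response_conditional_roc()`
anchors the curve at (0,0) and (1,1) and integrates by the trapezoidal
rule. Because tied ratings move together across the threshold, this area is
exactly the tie-corrected Mann-Whitney probability that a randomly chosen
correct trial carries higher confidence than a randomly chosen incorrect
one — the package carries an independent brute-force pairwise
implementation (`auroc_mwu()`) and the test suite verifies the identity on
a thousand randomized instances to 1e-12. The area is therefore invariant
under any strictly monotone transform of the confidence scale, so the
analysis does not depend on how participants use the analog scale, only on
its ordering. Whether thresholds use ≥ or > is immaterial for the area
under this tie-grouped construction.

The 20-bin summary of confidence (`bin_confidence()`), tailored to each
participant's dynamic range, is for visualization only; areas are always
computed from unbinned ratings. Curves are per participant and never pooled.

## The equal-variance SDT control (H3)

A response bias alone can produce a nonzero ΔAUC in an observer with no
metacognitive asymmetry whatsoever. H3 therefore compares the empirical
ΔAUC with the value an ideal equal-variance SDT observer would produce,
matched to the participant in three respects:

1. **Sensitivity and bias.** `estimate_sdt()` fits d′ = z(HR) − z(FAR) and
   c = −(z(HR) + z(FAR))/2 from the choice data, with c measured from the
   midpoint between the evidence distributions. Rates of exactly 0 or 1 are
   replaced by 1/(2N) and 1 − 1/(2N); a log-linear alternative
   ((k + 0.5)/(N + 1)) is available via the `correction` argument. The
   choice matters little here because d′ and c enter only through smooth
   tail ratios.
2. **Error-confidence distribution.** The model curve is evaluated at the
   participant's own empirical cumulative incorrect-confidence proportions,
   not at a refitted set of confidence criteria.
3. **Confidence-as-distance.** The model observer's confidence is any
   monotone function of the distance between evidence and criterion, which
   is all the type-2 analysis is sensitive to.

Under these assumptions the model's type-2 hit rate has a closed form: for
S1 responses (evidence above criterion), the type-2 criterion θ ≥ c that
reproduces a cumulative incorrect proportion `p` satisfies
P(x > θ | S2) = p · P(x > c | S2), which inverts exactly through the normal
quantile function; the expected correct proportion is then
P(x > θ | S1)/P(x > c | S1), with the mirror construction for S2 responses.
No root-finding or simulation is needed; `expected_type2_hr()` is exact to
quantile-function precision, and the tests check it against a 10^7-trial
Monte-Carlo observer. When the criterion sits at the distribution midpoint
the two model curves coincide, so the matched asymmetry is exactly zero for
an unbiased observer.

`asymmetry_beyond_sdt()` returns ΔAUC − ΔAUC_matched. On data simulated
from an equal-variance observer with a deliberately conservative criterion,
the empirical ΔAUC is clearly nonzero while this difference stays at zero
within Monte-Carlo error — the control absorbs exactly the bias-induced
component. On unequal-variance data it is reliably positive.

## Inference: one-tailed t-tests and JZS Bayes factors

Each hypothesis is tested with a one-sample one-tailed t-test at α = 0.05
on the participant-level differences, with Cohen's d = mean/sd, and a
Jeffreys–Zellner–Siow Bayes factor with a Cauchy prior of scale 0.65 on the
standardized effect. `jzs_bf()` integrates the noncentral-t likelihood over
the prior after the substitution δ = r·tan(θ), which maps the real line to
a bounded interval and turns the Cauchy weight into a constant; the
integrand is rescaled by its maximum on a probe grid so that arbitrarily
extreme t statistics cannot overflow. The quadrature is checked against a
dense-grid Riemann sum (2×10^5 points) to three significant figures and
against an independent open-source implementation during development.

The pre-registration does not state the sidedness of its Bayes factor.
Because H1–H4 are directional, the confirmatory battery defaults to a
positive half-Cauchy prior oriented along each alternative
(`bf_sided = "directional"`; H4's t statistic is negated first); the
two-sided prior is exposed as an option and both satisfy the quadrature
identity BF_two_sided(t) = (BF_dir(t) + BF_dir(−t))/2.

## Design analysis

`power_one_tailed()` is the exact noncentral-t power; at the planned
n = 106 and d = 0.32 it returns 0.948, i.e. 95% to two decimals.
`bf_design_sim()` reproduces the Bayes-factor outcome proportions by
simulation: 10,000 repetitions, each drawing 106 standardized differences
around a true effect that is either zero or Cauchy(0, 0.65)-distributed,
and computing the JZS Bayes factor of the resulting t statistic. The
planning Bayes factor is two-sided by default: under a true null the
two-sided BF favors the alternative only when |t| crosses a fixed
threshold (|t| ≈ 2.13 for BF10 > 1 at n = 106), giving the ~95%
null-support rate that motivates the design; the directional variant is
available for sensitivity analyses. Because the Bayes factor at fixed n is
a deterministic function of t, these proportions are central- or
noncentral-t tail probabilities in disguise, and the simulated values
stabilize to within the binomial Monte-Carlo error reported alongside
(≤ 0.5 percentage points at 10^4 repetitions).

## The synthetic cohort generator

`simulate_cohort()` emulates the deposited trial table: 96 trials in 6
blocks per participant, a fresh 1-up-2-down staircase per participant
(multiplicative step 0.9, starting at 30 ms), stimulus drawn equiprobably,
and a per-participant comprehension flag. The observer model is the
unequal-variance account the asymmetry literature debates: S2 evidence is
Normal(0, 1), S1 evidence Normal(d′, σ_S1) with σ_S1 ≥ 1, response S1 when
evidence exceeds a criterion, and a small lapse rate (2%) flipping
responses so that the exclusion rules have something to catch.

Choices the task description leaves open, fixed here once:

* **SOA → d′ link.** A saturating hyperbola
  d′(SOA) = d′_max · SOA/(SOA + SOA_half), with d′_max = 3 and a 25 ms
  half-point: zero at zero, monotone, and with a single interpretable
  parameter. The staircase needs only a smooth monotone psychometric
  function. The stimulus-duration/SOA geometry of the masking display is
  not modelled; SOA is treated as the one effective-visibility variable.
* **Confidence.** A logistic squash of |evidence − criterion| (gain 1.5),
  plus Gaussian metacognitive noise (SD 0.6) added to the distance before
  squashing, clipped to [0, 1]. The task only fixes a continuous analog
  scale; any monotone mapping gives identical ROC areas, so the squash
  matters only through the noise and clipping.
* **Response time.** Lognormal with median log-RT decreasing in confidence
  (scale 900 ms, sdlog 0.35, slope 0.8 per unit confidence), reflecting the
  robust inverse confidence–RT relation; this is what makes H4 emerge from
  the same evidence model rather than being injected separately.
* **Population.** Between-participant Gaussian variation with
  σ_S1 ~ 1.15 ± 0.25 (truncated at the equal-variance bound 1),
  d′_max ~ 3 ± 0.4, criterion ~ 0.55 ± 0.15, 98% comprehension pass rate.
  The σ_S1 level was calibrated once so that the participant-level ΔAUC
  effect size lands near the pilot-scale regime (d ≈ 0.7) at 80 analysed
  trials; under these defaults fewer than 20% of simulated participants
  are excluded.

One master seed drives everything; per-participant sub-streams are derived
deterministically from it, so cohorts are bit-reproducible.

**What the generator does not emulate.** Real masking dynamics, stimulus
identity (the six stimulus pairs differ only as labels), key
counterbalancing, feedback screens, the 2000 ms minimum rating time,
within-session fatigue or learning, and any higher-order confidence
computation beyond distance-to-criterion plus noise. Passing tests
demonstrate that the pipeline recovers the structure this generator
embodies — not that human data obey it.

**A staircase caveat.** With σ_S1 = 1, noise-free confidence and the
criterion at the distribution midpoint, a *stationary* observer's ΔAUC is
symmetric about zero (the two response conditions are mirror images), and
the test suite verifies this with a sign test over 1,000 simulated
participants. The full staircased session, however, makes d′ drift between
trials while the criterion stays fixed, which leaves a small positive group
ΔAUC (~0.03) even under equal variance. This is a real property of
staircased designs worth keeping in mind when interpreting small
asymmetries; it stays an order of magnitude below the unequal-variance
effect the study targets.

## Rejection criteria and their edge cases

Trials: block 1 dropped (only the last five blocks are analysed); RT
outside [250 ms, 5 s] dropped. Participants: accuracy below 60%; RTs
outside the window in more than 25% of trials; failed comprehension check;
fewer than two errors of either error type (type-2 curves need incorrect
responses on both sides). The RT-proportion rule is evaluated on all
trials, as registered; accuracy and error counts are evaluated on the
analysed trials, since those feed the ROC — the registration does not say
which set these use, and this choice keeps the inclusion rule aligned with
what is actually analysable. RT logs are natural; the base only rescales
both sides of H4 jointly and leaves t, p and d unchanged. The comprehension
check is modelled as a single boolean (retries are not specified).

## Numerical notes and problem sizes

ROC construction is O(n log n) (sorted unique thresholds, cumulated tie
counts), exact for ties; trapezoid integration throughout. The JZS
quadrature uses relative tolerance 1e-6 with a 257-point probe for the
integrand peak. Degenerate inputs fail loudly: empty confidence classes
point to the upstream exclusion rule, zero-variance difference scores and
cohorts with fewer than three included participants are errors, identical
confidence ratings collapse the 20-bin histogram to one degenerate bin with
a warning.

The test suite exercises the heavy Monte-Carlo checks at sizes chosen to
make their standard errors decisively smaller than the effects under test:
10^4-repetition design simulations, 10^7-trial oracle checks for the
expected type-2 hit rate, 40-participant × 3×10^4-trial cohorts for the
control-validity property, and 2–3×10^4-trial staircase convergence runs.

## Limitations

The package pre-registers auROC as the only metacognitive-sensitivity
measure: no meta-d′, no hierarchical models, no unequal-variance fitting to
real data, and no meta-analysis across the six stimulus-pair experiments.
The matched-SDT control conditions on the empirical error-confidence
distribution as registered; other operationalizations of "matched
confidence distributions" are conceivable and would give slightly different
H3 statistics.
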