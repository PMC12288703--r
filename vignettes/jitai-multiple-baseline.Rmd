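---
title: "Methods: randomization inference for multiple-baseline JITAI trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: randomization inference for multiple-baseline JITAI trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`jitaisim` analyses single-case AB trials in which a just-in-time
adaptive intervention (JITAI) starts on a randomized day, and simulates
such trials with known ground truth. This vignette is the package's
account of the underlying statistics: the models, the defaults and why
they are what they are, the numerical conventions, and what the
simulations can and cannot tell you about real data.

## The design and its randomization space

A trial runs for `total_days` (default 28). Each day carries three
momentary stress prompts (11:00, 16:00, 21:00), one morning busyness
forecast (07:00), and one evening delivery slot (19:00) for the exercise
the morning forecast triggered. The baseline (A) phase lasts `L` days
with `L` randomized in `baseline_min..baseline_max` (default 7–14); the
intervention (B) phase covers the remainder. Days are 1-based, the
"start day" is the first B day (`L + 1`), and phase boundaries fall
between days — all inference is at day resolution, clock times are
metadata.

The randomization of `L` defines the *admissible start set*
`S = {baseline_min + 1, ..., baseline_max + 1}` (default `{8..15}`,
eight elements). This set is the entire justification for the exact
test below, so the package treats it as a first-class object
(`enumerate_start_days()`).

Two baseline-assignment modes exist because cohort tables of this
design often show each admissible length exactly once while the
randomization argument only needs independent uniform draws.
`balanced_permutation` (default for cohort emulation) shuffles the full
range once per block of participants; `iid_uniform` draws
independently and is the default inside the power simulations, matching
the joint-null sampling of the combined test. The combined test treats
participants' starts as independent either way: its validity argument
conditions on each participant's admissible set, not on the cohort-level
balancing.

## Decision rules

The tailoring variable (momentary stress, or forecast busyness for the
morning cue) is a continuous 0–100 slider, but the shipped rule table is
printed in integer bands (0–39, 40–59, 60–79, 80–100). The bands are
implemented as half-open real intervals `[0,40)`, `[40,60)`, `[60,80)`,
`[80,100]`, which preserves the integer semantics at integer inputs and
gives every real response exactly one band (property-tested over a dense
grid including the edges). The lowest band recommends nothing.
Momentary cues map to breath control, mindfulness and progressive muscle
relaxation; morning cues to compassionate self-talk, cognitive defusion
and cognitive restructuring. Thresholds and pools are config-driven;
the defaults above are the shipped table.

Tutorial durations for the three momentary exercises are the published
video lengths (3.8, 9.0, 5.5 minutes). The morning exercises have no
individually published durations, only the overall 3.5–9.0 minute range,
so the catalog carries synthetic values (4.0, 6.0, 8.0) inside that
range; they are metadata only and never enter any computation.

The engine is stateless per prompt: nothing in the data available to us
describes whether a real system would suppress or repeat a
recommendation after an ignored prompt, so no such carry-over is
modelled. Engagement is a set per prompt (a participant may perform two
exercises, or something "other", or skip); dose tabulation counts each
distinct engaged exercise once per record, and an engaged exercise that
was not that prompt's recommendation counts as spontaneous.

## The synthetic cohort

The generator is deliberately the simplest process that contains the
features threatening the inference: autocorrelation, a phase-level
shift, an acute within-prompt effect, and non-response.

Latent momentary stress follows an AR(1) process around a person mean
across consecutive momentary slots,

$$X_t = \mu + \phi\,(X_{t-1} - \mu) + \varepsilon_t,\qquad
  \varepsilon_t \sim N(0, \sigma^2),$$

started from its stationary distribution, with `delta` slider units
subtracted throughout phase B and observed values clamped to `[0, 100]`.
The phase effect can be given as standardized `d`, converted through the
stationary marginal SD `sigma / sqrt(1 - phi^2)` so that `d` means the
same thing at any `phi`. Slot-level AR(1) dependence (rather than, say,
day-level random effects or circadian structure) is an artifact
convention: autocorrelation is the property that makes naive tests
anticonservative, and AR(1) is its minimal carrier.

Defaults describe a moderately stressed community cohort: `mu = 45`,
`sigma = 18`, `phi = 0.3` (configurable to 0 for iid checks), momentary
response probability 0.76 in baseline and 0.60 in the intervention
phase, morning response probability 0.44, `d = 0.8` (the middle of the
0.6–1.0 range the design is meant to detect), and an acute exercise
effect `gamma = 5` slider units with post-exercise report noise of SD 3.
Non-response is Bernoulli per prompt, i.e. missing completely at random;
this is a deliberate simplification — real participants answer when
they are available, a mechanism nobody has data to model here, and the
per-protocol filter downstream is the design's actual defence.

Engagement: a recommended exercise is performed with probability
`p_engage` (default 0.8), otherwise skipped; when nothing is
recommended a spontaneous exercise occurs with probability `p_spont`
(default 0.05). Performed exercises produce a post-exercise report
`clamp(pre - gamma + noise)`; skipped opportunities produce none.
Baseline prompts never carry recommendations (the trial is
single-blind).

Questionnaires (PSS, PHQ-9, GAD-7, RSQ brooding, HEMA subscales) are
drawn as totals near published cohort marginals, then distributed over
items within each instrument's valid range; post totals subtract an
instrument-specific change effect (default: 3.75 points of brooding,
nothing else) plus individual noise (SD 3.2, which makes the implied
standardized change for brooding land near the published effect size),
truncated to the valid range. Two marginals could not be taken at face
value: the published per-participant PSS entries exceed the 0–40 range
of the 10-item scale scored 0–4, so the generator uses an in-range
high-stress marginal (mean 33, SD 4, above the >31 "high stress"
reference point); likewise the published HEMA relaxation entries exceed
the 2-item 2–14 range, so an in-range marginal (mean 11, SD 2.5) is
used. Truncation means realized means sit slightly inside extreme
targets — the brooding post-score test allows for this.

Ground truth (assignment, `delta`, `gamma`, response probabilities) is
stored beside the data, and the test suite includes recovery checks:
the day-level A−B contrast recovers `delta`, and the mixed model
recovers `gamma`, each to within 5% under low-clamping settings
(`sigma = 12`, effects of 10 and 6 units, cohorts of 150 and 30).

## Preprocessing

Day-level aggregation averages the momentary values available that day;
in phase B a slot contributes the post-exercise report when one exists.
When the exercise was skipped the pre-exercise report is used instead —
discarding a responded prompt because no exercise followed would waste
data and bias the day mean toward engaged moments. A strict
`post_only` mode is available for sensitivity analysis. Days with no
usable response are missing, not imputed: momentary-level imputation is
not defensible at the compliance levels this design anticipates.

The per-protocol filter excludes a participant when either phase has
fewer than `min_obs_per_phase` (default 3) non-missing days — three to
five observations per phase being the practical floor for a
randomization test on a short series. Exclusions carry machine-readable
reasons.

Questionnaire scoring is plain summation with left-closed severity
bands (a total equal to a cutoff enters the band): PHQ-9 at 5/10/15/20,
GAD-7 at 5/10/15. Reported percentages (compliance, endorsement) are
rounded half-up to one decimal; internal computation is never rounded.

## The randomization tests

The test statistic for start `s` is
`D(s) = mean(days >= s) - mean(days < s)` over non-missing days —
intervention minus baseline, so stress reductions are negative. The
individual exhaustive p-value ranks the observed `D` within
`{D(s) : s in S}`; ties count as "less than or equal", and the observed
assignment is a member of its own null set, so `p >= 1/|S|`. With the
default eight starts the best attainable individual p is 0.125 — above
any conventional α, which is the quantitative reason individual tests
in this design are descriptive at best and the combined test carries
the inference.

The alternative defaults to `less` (the intervention is supposed to
reduce stress); `greater` and `two_sided` (ranking `|D|`) are
available. Sidedness is a genuine judgment call in this design; the
directional default matches the direction of the scientific hypothesis
and the "equal to or smaller" ranking convention.

Monte Carlo tests sample starts uniformly with replacement and use the
add-one estimator `p = (1 + count)/(R + 1)`, which is strictly positive
and yields a valid test regardless of `R`. Exhaustive and Monte Carlo
paths are checked against each other on enumerable instances, and both
against an independent brute-force oracle.

The combined statistic is the unweighted mean of per-participant `D_i`.
Its null distribution is the product space of individual start sets,
enumerated exactly when its size is at most `exhaustive_cap`
(default 10^6; seven participants with eight starts each, 8^7 ≈ 2.1
million, already exceeds it) and sampled otherwise. A permuted start
that would leave a phase with no observed days is dropped from the
exhaustive set, with a warning; day-level aggregation exists precisely
to make this rare.

Null calibration is verified by simulation in the test suite: with
`delta = gamma = 0`, the rejection rate at α = .05 over 600 null
cohorts lies within the 95% binomial interval around .05, for the
combined test (three-participant cohorts, exhaustive 8^3 space) and for
the individual test on a widened design (baseline 3–22, twenty starts,
so α is attainable at exactly 1/20).

## Effect models

The acute pre/post exercise contrast is a two-level linear model —
stress on time (pre vs post) with a random intercept per participant —
estimated by maximum likelihood, with Satterthwaite degrees of freedom
as implemented in `lmerTest` (the specific small-sample approximation
is named in the model metadata; any recognized approximation would do,
and fractional df are expected output). On balanced complete data the
fixed effect reduces to the grand mean of within-observation
differences, which the tests assert to numerical precision. The model
uses every prompt with both a pre and a post value; whether to restrict
to engaged prompts only is a judgment call, and the pairing rule used
here is the more inclusive one.

Two Cohen's dz conventions coexist deliberately. For paired
questionnaires, `dz = mean(diff)/sd(diff)` with `diff = pre - post`
(positive = improvement), `t = dz * sqrt(n)`, two-sided p on `n - 1`
df — cross-checked against `stats::t.test(paired = TRUE)`. For the
multilevel acute contrast, dz is the mean of participant-level mean
differences divided by their SD across participants: it respects
clustering but is *not* comparable to the questionnaire dz, and with a
handful of highly consistent participants it can be numerically large
while the mixed-model p stays modest. It is reported as an
interpretation, not as a reproduction of any published convention,
which could not be inferred.

## Power simulation

`estimate_rejection_rate()` chains generator → aggregation →
per-protocol filter → combined Monte Carlo test per replicate and
reports the rejection fraction with a normal-approximation interval.
Defaults are 200 replicates and `R = 500` permutations per test: 500 is
enough resolution around α = .05 inside a loop, while a single
confirmatory analysis would use 5000. Replicate and grid-cell seeds are
derived from the base seed through an integer-stream split, so cells
are independent and every run is exactly reproducible.

The headline check (also in `scripts/acceptance.R`) estimates power at
`d = 1.0`, ten participants, `phi = 0`, full compliance over the
default design — the favorable end of the 0.6–1.0 / 6–10-participant
envelope the design targets — and the test suite requires it to reach
0.80. Day-level aggregation of three prompts shrinks within-day noise
by √3, so the day-level standardized effect exceeds the slot-level `d`;
power at these settings is correspondingly high.

## Known limitations

* The generator has no circadian, weekday or event structure, no
  response-time information, and missingness is MCAR by default (a
  stress-dependent response probability can be configured). Passing
  tests demonstrate correctness of the machinery under this process,
  not robustness to every real-world mechanism.
* The AR(1) convention ties consecutive momentary slots across day
  boundaries; nothing in day-level inference depends on this, but
  slot-level analyses should treat it as a modelling choice.
* The combined test assumes independent uniform starts; cohorts built
  with `balanced_permutation` mildly violate independence, which makes
  the test slightly conservative rather than invalid.
* Individual tests in the default design cannot reach α = .05; they are
  reported for completeness and visual context.
* Effect-size confidence intervals by test inversion, and other
  single-case statistics (Tau-U, NAP), are out of scope.
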