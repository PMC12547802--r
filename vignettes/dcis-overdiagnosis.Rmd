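---
title: "Modelling DCIS overdiagnosis in population-based screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DCIS overdiagnosis in population-based screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(overdcis)
```

## The problem

Ductal carcinoma in situ (DCIS) is a non-invasive breast lesion detected
mostly by mammography screening. Because DCIS is treated whenever it is
found, its natural course — how often it regresses, persists, presents
clinically, or progresses to invasive breast cancer (IBC) — cannot be
observed directly, and neither can overdiagnosis: the detection of lesions
that would never have surfaced in a woman's lifetime without screening.
Micro-simulation makes the counterfactual explicit. This package simulates
each woman's latent disease history twice — once under a screening
programme and once without — from *identical* random draws, so the excess
diagnoses in the screened arm are attributable to screening alone.

## The model

Time advances in annual cycles from birth (age 0) to a horizon
(`max_age`, default 100). A woman is in one of the transient states
healthy or DCIS (grade 1, 2 or 3), or in an absorbing state: death from
other causes, screen-detected DCIS, clinically detected DCIS, or IBC with
a DCIS precursor. Diagnosis is absorbing — follow-up ends at the first
diagnosis, and no post-diagnosis survival is modelled. IBC arising
without a DCIS precursor is out of scope; it does not enter any DCIS
overdiagnosis quantity.

Within each cycle, events are tested in a fixed order
(`cycle_event_order()`): other-cause death, DCIS onset (healthy women
only), screening exam (if one is scheduled and DCIS is already present),
clinical detection, progression to IBC, regression to healthy. The first
event that fires ends the cycle. Two consequences of this convention are
worth spelling out:

* a lesion cannot be screen-detected in the year of its onset — onset is
  itself a transition and ends the cycle; detection can happen from the
  next scheduled exam onwards;
* at an exam age the exam is tested before clinical detection, so a
  prevalent lesion at an attended exam is preferentially screen-detected.

The chain's nine inputs are an other-cause mortality schedule `q(a)`, an
onset schedule `h(a, g)` (annual probability that a healthy woman
develops grade-`g` DCIS at age `a`), a progression schedule `p(a, g)`,
and four scalars: regression (0.05/year, independent of age and grade),
clinical detection (0.05/year while DCIS is present and undetected),
screen sensitivity (0.86 per attended exam) and participation (0.76 per
invitation). The screening policy is biennial invitation at ages 50–75
(13 exams at ages 50, 52, …, 74). Regression returns a woman to the
healthy state with the onset hazard intact, so repeat episodes are
possible; grade is assigned once at onset (proportional to `h(a, ·)`) and
never changes, since grade progression within DCIS is not part of the
model.

The published sources report the regression and clinical-detection
parameters as bare percentages without a time basis; here both are
interpreted as *annual per-cycle* probabilities, consistent with the
yearly cycle, and the interpretation is isolated in the scalar parameters
so an alternative (per-episode, lifetime fraction) could be swapped in
behind the same interface. Participation is likewise a per-invitation
Bernoulli draw, independent across rounds: the source compliance figure
is an overall rate, and habitual-attendance correlation is a known
omission (see Limitations).

### Common random numbers

Every random quantity derives from a single run seed through named
substreams keyed by (seed, cohort, stream, age): natural-history draws
(death, onset/grade, clinical detection, progression, regression) in one
stream, screening draws (attendance, detection) in another. Both arms of
a pair consume the natural stream identically; only the screened arm
touches the screening stream. This makes the unscreened arm of a pair
bit-identical to a standalone unscreened run, makes results independent
of execution order, and enforces the interception property — a woman's
screened-arm diagnosis can only be earlier than (or equal to) her
unscreened-arm diagnosis, never later — which the engine asserts on every
paired run.

### Horizon

The last cycle runs at `max_age`; any woman still alive and undiagnosed
afterwards is censored without diagnosis (mode `NONE`, as for other-cause
death). Generated calibrations set `q(max_age) = 1`, so in practice the
horizon coincides with certain death; keeping censoring as the formal
rule lets small hand-calculable chains with `q = 0` remain valid inputs,
which the verification oracle's worked examples rely on.

## Overdiagnosis definitions

For a definition with numerator modes `M` (always including screen
detection) and an age window `W`:

* **number** = diagnoses with mode in `M` and age in `W` in the screened
  arm − diagnoses with mode in `M \ {screen}` and age in `W` in the
  unscreened arm;
* **rate** = number / (women attending ≥ 1 exam) × 100,000;
* **proportion** = number / (denominator-mode diagnoses in the screened
  arm within `W`).

Definition A counts screen-detected, clinically detected and progressed
(IBC) DCIS; B drops progression; C keeps screen detection only. The
perspectives are INDIVIDUAL (screening start to screening end),
POPULATION (screening start to horizon; the base) and LIFETIME (birth to
horizon). Perspective *names* are authoritative throughout: numeric codes
are accepted with a warning because the literature numbers them
inconsistently. Since the arms are identical before age 50, the
overdiagnosed *number* is the same from the population and lifetime
perspectives, and the lifetime proportion can only be lower.

Two structural facts follow directly from the subtraction form and are
exercised by the test suite: within a perspective the proportions order
A ≤ B ≤ C, and definition C's proportion is identically 1 — no screen
detections exist without screening, so nothing is subtracted. Published
estimates that report "screen-detected only" proportions below 100 %
use additional assumptions (e.g. linking individual counterfactual
fates) that the subtraction form does not encode; the labelled
`B/A` variant (B numerator over the full A denominator) is provided as
the explicit interpretation of "excluding progression from
overdiagnosis while counting it as diagnosed".

Per-grade estimates apply the same arithmetic within grade and always
sum to the totals. An empty denominator yields an undefined (`NA`)
proportion, never zero.

## The exact oracle

`oracle_mode_probabilities()` propagates the full state distribution of
the same chain age by age — healthy plus three DCIS grades, each split
by ever-screened status — applying the identical event order, and returns
exact expected terminal-mode probabilities by grade and age.
`oracle_overdiagnosis()` combines the two arms exactly as the
Monte-Carlo estimator does; this is the expectation of the paired
estimator because expectations are linear and pre-screening dynamics are
arm-identical. The oracle is the package's independent verification
route: Monte-Carlo terminal-mode frequencies are required to agree with
it within three binomial standard errors at n = 500,000, and the tornado
endpoints are checked against it the same way.

## Synthetic calibration

Registry-derived input tables are not redistributable, so
`generate_synthetic_calibration()` builds stand-ins that reproduce the
qualitative structure the model needs:

* Gompertz mortality `q(a) = b0 exp(b1 a)` with `b0 ≈ 3e-5`,
  `b1 ≈ 0.094`, giving roughly 0.3 % annual mortality at 50 rising to
  ~25 % in the mid-90s, absorbing at the horizon;
* a Gaussian-shaped onset curve, zero before age 25, peaking between 55
  and 70, with a lifetime onset mass of 2.2–3.0 % split across grades
  roughly 24/40/36 %;
* progression increasing in grade and mildly in age, with base annual
  probabilities 0.012 / 0.026 / 0.050 for grades 1/2/3. This level was
  chosen once, using the exact oracle, so that in an unscreened cohort
  roughly 20 % of DCIS episodes end in IBC — the design target for the
  model's natural history (an episode here is one onset; episodes ending
  in regression, death or the horizon count in the denominator);
* the four scalars at their defaults above.

The seed perturbs the shape hyper-parameters within the narrow ranges
given, so every seed yields a distinct but valid calibration; seeds do
not move the qualitative structure. What the generator does *not*
emulate: secular trends in incidence, individual risk factors
(mammographic density, hormonal factors, family history), grade
misclassification, and correlation between attendance rounds. Passing
tests therefore demonstrate that the estimation machinery is correct for
a population with this structure, not that the synthetic population is
the Dutch one; reproducing published registry-calibrated estimates
requires supplying the original tables via `read_calibration()`.

## Sensitivity analyses

Each of the seven parameters — the four scalars plus one multiplicative
factor per schedule (per-age confidence intervals are not available, so
a schedule moves as a block) — carries an interval. When no externally
derived 95 % CIs are supplied, the defaults are ±40 % relative for
scalars (clipped to [0, 1]) and factors 0.8/1.2 for schedules; these are
documented stand-ins, configurable through `cal$intervals`.

The univariate analysis re-runs the paired simulation with one parameter
at a bound and the *same* seed (common random numbers), so a zero-width
interval produces an exactly zero-width tornado bar. The probabilistic
analysis (default 100 runs) draws every parameter independently and
uniformly within its interval — the sources do not state a sampling
distribution — and uses a distinct sub-seed per run so parameter and
sampling noise are both represented; pinning `use_base_seed = TRUE`
recovers the base estimate exactly when intervals are degenerate.

## Problem sizes and numerical choices

The headline analysis uses the full design of 10 replicate cohorts of
100,000 women; summaries report the mean over cohorts with the min–max
range. The sensitivity analyses repeat the whole simulation many times
and therefore run on reduced cohorts by default (50,000 for the tornado,
20,000 per PSA run, one cohort each), which keeps the Monte-Carlo error
of a proportion near half a percentage point while making a full
analysis a couple of minutes on one core. Uniform draws are compared
with strict `<` against probabilities, grade assignment inverts the
cumulative onset vector with `findInterval`, and the oracle checks
probability-mass conservation to 1e-12 at every run.

## Interface

This is an R analysis package: the exported functions compose the whole
pipeline, and `run_pipeline()` writes every report artifact (calibration,
Table-2-style summary, definition grid, tornado and PSA tables) with the
seed and a configuration hash embedded in each file, so a shell-level
entry point would only wrap `Rscript -e`. Reruns of an identical
configuration are byte-identical.

## Limitations

No breast-cancer-specific mortality, treatment, or cost-effectiveness;
no direct healthy-to-IBC pathway (irrelevant to DCIS overdiagnosis but
relevant to total IBC counts); no within-DCIS grade progression; no
attendance correlation across rounds; and the synthetic calibration is a
structural stand-in, not a fitted population. Lead time appears only
implicitly, through the counterfactual pairing.
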