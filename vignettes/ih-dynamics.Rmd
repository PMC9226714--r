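---
title: "Modelling the subjective course of idiopathic hypersomnia as a system of target-seeking levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the subjective course of idiopathic hypersomnia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihsim)
```

## The model

Idiopathic hypersomnia (IH) is diagnosed from a single time point, yet the
burden a patient experiences unfolds over decades. `ihsim` treats that
unfolding as a system-dynamics problem: each clinical phenomenon captured in
a structured interview becomes a *level* (stock) that seeks a time-varying
*target* through a balancing feedback loop with an adjustment time, and the
patient's overall experience of the disease is itself a level whose target
is the sum of all the others.

Concretely, a level with value $PV_t$, target $g_t$ and adjustment time
(delay) $d$ evolves on a one-year clock by explicit Euler:

$$PV_{t+1} = PV_t + \delta_t, \qquad
  \delta_t = \operatorname{cap}\!\left(\frac{g_t - PV_t}{d},\, g_t\right).$$

The uncapped rate is the goal gap divided by the adjustment time — the
classic target-seeking loop, converging geometrically as
$g + (IV - g)(1 - 1/d)^t$ for a constant target. The cap bounds a single
year's movement by the target value itself.

### The two rate-cap modes

The cap admits two readings, and the package implements both:

* **`literal`** — $\delta_t = \min(\text{raw}, g_t)$, a signed minimum. For
  positive targets this caps fast approaches; for *negative* targets,
  however, the signed minimum always selects a value at or below $g_t$, so
  the level overshoots and runs away from the goal. A level chasing
  $g = -50$ from 0 with $d = 2$ takes rate $\min(-25, -50) = -50$.
* **`symmetric`** (default) —
  $\delta_t = \operatorname{sign}(\text{raw})\,\min(|\text{raw}|, |g_t|)$
  (raw rate when $g_t = 0$), which preserves the target-seeking character
  for targets of either sign.

Half of the modelled phenomena live exclusively in the negative range
(depression, pain, impairment), so a repelling negative target contradicts
the balancing-loop description of the dynamics; we therefore default to
`symmetric` and retain `literal` for fidelity experiments. Neither mode is
asserted as "correct" in the tests — the engine tests pin each mode to its
own definition.

The symmetric closed form holds only while the cap never engages, i.e. while
the initial gap is within $d\,|g|$; under capping the approach is linear at
rate $|g|$ per year and the gap still shrinks monotonically for $d \ge 1$.
The engine tests sample the uncapped basin when asserting the geometric
form and sample unrestrictedly when asserting monotonicity.

## Dynamization: from interview answers to target schedules

Every input parameter is normalized onto a common scale before entering the
model. Continuous and ordinal values map linearly from their instrument
range (ESS 0–24, BDI-II 0–63, …) onto $[0, 100]$ — ordinal categories land
evenly spaced — and binary presence maps to $\{0, 100\}$. Signed polarity
then places the target in $[-100, 100]$: phenomena like depression are
always negative; naps or nocturnal sleep quality are positive when the
patient perceived them as refreshing and negative otherwise
(`data_dependent`). Where a parameter declares no instrument range, a
cohort-observed range may be supplied; the instrument range is the default
because it keeps normalization independent of the particular data set.

A dynamic parameter's history — first occurrence, extremes, last
occurrence, dated change events — becomes a per-year target: zero outside
the active window, the normalized extreme value inside it, stepping through
change events. Between events the target is piecewise-constant by default;
a `linear` mode ramps instead, since the interview's "rate of change"
qualifier fixes no functional form. Values mildly outside the declared
scale are clamped with a warning rather than rejected, which is the
realistic treatment of retrospective interview data.

Medication is dynamized with a persistence tail: the target equals the
normalized perceived effect during administration and decays linearly to
zero over one simulation year after discontinuation (the year after
stopping carries half the effect). One year is the shortest representable
"short while" on a yearly clock.

Calendar years are kept throughout; step 0 is the onset year and the
horizon is the re-evaluation interview.

## Aggregation and the parameter registry

The 71 input parameters enter the model in extenso, but the simulation's
outputs are twelve aggregate state variables (anxiety, depression, sleep
inertia, work and social impairment, sleepiness, fatigue, naps, nocturnal
sleep, other psychiatric disorders, somatic pathologies, and the two
stimulant effects). Members combine by per-year mean by default — the mean
preserves the $[-100, 100]$ scale — with a clamped sum available. The
shipped registry (`inst/extdata/parameter_registry.csv`) is editable data:
the somatic aggregate has its published 24 members and naps its published
6; the remaining 41 assignments are by clinical face validity. Nap-related
sleep inertia is a separate input parameter belonging to the sleep-inertia
aggregate, not a modifier of the naps aggregate, so refreshing naps
followed by sleep drunkenness are representable.

Per-aggregate adjustment times default to 1 year for the fast-acting
variables (naps, the two medication effects), 2 for the core sleep symptoms
and 3 for slowly shifting burdens (depression, somatic disease, social
impairment); records may override them. The experience loop's own delay
defaults to 1 year.

## Scenarios

* `baseline` — every patient, full disease duration.
* `last5` — the final five yearly values of each trajectory; patients with
  duration under five years are excluded (a one-year disease course cannot
  contribute a five-year window).
* `medicated_only` — the `last5` window restricted to patients with a
  methylphenidate or modafinil episode overlapping it.

Windowing only selects patients and years; it never alters values. Note the
medicated group is a subset of the last-5 group, as the published column
headers imply; the Mann–Whitney comparison between them is therefore not a
comparison of independent samples, and its p-values should be read with
that caveat.

## The derivative-sign fit

On a yearly grid the only defensible derivative estimator is the first
forward difference. Each segment of both waveforms is classed decreasing /
constant / increasing; the fit is the percentage of segments whose classes
agree. The constancy tolerance defaults to 1% of the pooled range of the
two series: a visually flat segment with a small positive slope is
analytically increasing, and a strictly zero tolerance would class almost
every floating-point segment as non-constant. The tolerance is
configuration-exposed.

The cohort-level figure pools segments (total matches over total segments)
rather than averaging per-patient percentages, so it measures pattern
fidelity, not the number of patients who matched; the unweighted mean is
available as an option.

## The synthetic cohort generator

The study's raw interview records are not deposited, so the package ships a
generator whose defaults reproduce the published marginal structure:

* demographics and sleep variables are drawn from piecewise-linear inverse
  CDFs anchored at the published quantiles, with anchor points added at the
  published threshold proportions — the 24-h sleep anchors are
  $\{0 \to 603,\ 0.214 \to 660,\ 0.5 \to 690.5,\ 1 \to 1100\}$ so that the
  median is 690.5 min and 78.6% exceed 660 min; ESS anchors place 85% above
  10; MSLT anchors place 73.8% below 8 min. The published IQRs would
  over-constrain a piecewise-linear CDF and serve as soft checks only;
* disease duration is the difference of the interview-age and onset-age
  draws, rejecting durations under one year;
* comorbidities are independent Bernoulli draws at the published
  frequencies; core sleep/impairment symptoms are present with probability
  0.8; anxiety/depression sub-symptoms appear only alongside their
  diagnosis;
* stimulant episodes fall in the last five pre-interview years at the
  published uptake (33/40), with perceived effects mostly positive;
* marginals are sampled independently — the generator imposes no joint
  structure, a documented limitation: passing calibration tests says the
  marginals are right, not that between-symptom correlations resemble real
  patients.

Reported courses come in two modes. `self_consistent` copies each patient's
simulated experience verbatim, making the pooled fit 100% by construction —
the end-to-end smoke test. `template_noisy` emulates imperfect retrospective
testimony: the report preserves the simulated course's segment-class
sequence with each class independently corrupted with probability
`report_noise` (a corrupted class always differs), then re-synthesised as a
series; the nearest of the nine plotted templates is recorded as the
patient's template choice. We deliberately corrupt the class sequence
rather than substituting the rendered template itself: the nine canonical
shapes are stand-ins (their exact published plots are not available) and
match realistic target-seeking output at only ~35–60% of segments, which
would dominate the statistic with template-choice error and destroy the
interpretability of `report_noise` as a fidelity dial. With the chosen
design the expected pooled fit degrades as $100(1 - q)$, so $q = 0$ gives
~100%, $q = 1$ gives ~0%, and $q = 0.25$ lands in the 70–80% band — the
fidelity regime reported for real cohorts — without asserting any
particular published number.

The nine templates themselves are canonical: linear monotone courses,
two-phase courses switching at mid-duration, and 4-year-period oscillations
at ±10 (slight) and ±40 (strong).

## Contribution statistics

Per scenario, each aggregate's signed sum is its level values summed over
patients and windowed years; the absolute contribution is
$100\,|s_i| / \sum_j |s_j|$, rounded half-up to one decimal for display
parity with the published layout (R's own `round` is half-even). The
scenario comparison runs a Mann–Whitney test per aggregate on per-patient
windowed sums (per-patient means are available); p-values are exact when
there are no ties and $n_1 n_2 \le 400$, otherwise normally approximated
with tie and continuity correction. No multiple-testing correction is
applied, matching the original analysis.

## Numerical choices and problem sizes

Integration is explicit Euler at the model's own one-year step with no
sub-stepping — the clock is part of the model, not a solver tolerance.
Schedules are validated to cover the simulated window exactly. Template
tie-breaks take the lowest template id. The test suite runs the full
pipeline at cohort sizes 5–43, the noise sweep at 40 patients × 10 seeds,
and generator calibration at n = 3,000 (tests) and n = 10,000 (acceptance
script), sizes at which the calibrated marginals are recovered to within
1–2% while the whole suite stays fast.

## Limitations

The registry's unpublished 41 parameter assignments, the per-aggregate
delays and the generator's presence probabilities are clinically plausible
choices, not estimates; the synthetic cohort validates the machinery, and
its contribution tables should not be read as clinical findings. The
simulated scenario comparison inherits the subset (non-independence)
caveat above. Gray-listed mechanisms of the original causal diagram (GABA
signalling, the circadian rhythm generator) are outside the simulated
structure here as they were in the source model.
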