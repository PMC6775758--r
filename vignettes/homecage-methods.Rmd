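---
title: "homecage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{homecage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`homecage` models a continuously running home-cage auditory training rig:
a task engine that schedules and adjudicates trials around the clock, a
generative virtual mouse standing in for the cage of live animals, an
analysis suite for the resulting event logs, and a speaker-whitening
calibration. This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions taken where the behaviour of
such rigs is under-specified.

## The task engine

Each trial lasts 4 s: 1 s of silence, a 1 s pure tone, 2 s of silence. The
behavioural response window is the 3 s from tone onset, so together with
the prestimulus second it tiles the whole trial: any trial containing a
lick is classified by its *first* lick as **early** (before the tone),
**hit**/**false alarm** (target/nontarget, inside the window), and trials
without licks are **misses**/**correct rejections**. Hits open the reward
valve for 2 s (0.075 ml); early licks and false alarms add a 20 s timeout
to the next intertrial interval (in detection and discrimination; shaping
punishes nothing and auto-rewards 20% of trials 0.5 s after tone onset).
Silent probe trials are adjudicated against the target rule for
bookkeeping but are never rewarded and never punished.

Two constraints gate the start of the next trial: an ITI drawn uniformly
on 5–9 s (plus any timeout), and a lick-refrain requirement drawn uniformly
on 5–25 s (exactly 5 s in shaping). Their composition is not fully
determined by the usual description of such rigs; `homecage` takes the
minimal reading: the trial starts at the earliest time that is both past
the ITI (+timeout) and at least one refrain-draw after the cage's last
lick, with both values drawn once per trial. Licking during the ITI per se
does not reset the ITI; it only matters through the refrain window.
A lick *exactly* one refrain before the candidate start satisfies the
constraint; a 10⁻⁶ s tolerance keeps that boundary robust to floating-point
round-off. When `schedule_next_trial()` is called directly, a configurable
30-minute cap turns a lick source that never stops licking into a
diagnosable error; inside `run_session()` the horizon is the remaining
session, because the only in-session consequence of unbroken licking is a
later trial.

All lick times live on the sensor's 30 ms grid; events that quantize onto
the same grid point merge, because the hardware cannot distinguish them.
One root seed drives independent named substreams (ITI, refrain, stimulus
category, auto-reward, mouse behaviour, background licking), so a fixed
seed reproduces a session byte-identically and changing one draw path does
not perturb the others.

## The virtual mouse

The cage is modelled as a single agent producing a merged lick stream —
the rig cannot attribute licks to individuals, so only the merged stream
is observable. The stream has three components:

1. **Spontaneous Poisson licking.** An inhomogeneous Poisson process (by
   thinning) at rate `n_mice × spont_rate × circadian_drive ×
   engagement_level`, with separate dark/light base rates. With circadian
   sharpness 0 and the oscillation disabled this reduces to a homogeneous
   Poisson process, which the tests verify against the closed-form count
   distribution.
2. **Spout-contact episodes.** An alternating-renewal process of contact
   episodes (exponential durations and gaps, dark/light-specific means)
   during which the cage licks at ~2 Hz: drinking and grooming bouts in
   the dark, long sleeping-contact episodes in the light. Episodes matter
   in two ways: their licks block trial initiation through the refrain
   rule, and an episode that begins mid-trial registers as a response.
   This component exists because a memoryless (Poisson) process cannot
   both throttle trial initiation (which needs sustained licking) and keep
   trial engagement low (which needs sparse licking); a cage's real
   spout-contact behaviour is bouty, and the bout structure is what
   reconciles hundreds of initiated trials per day with only tens of
   engaged ones.
3. **Per-trial responses.** With probability `p_early × drive ×
   engagement` the cage licks at a uniform time in the prestimulus second
   (keeping the early rate directly tunable); otherwise, with probability
   `p_hit_given_engaged` (target) or `p_fa_given_engaged`
   (nontarget/probe) times the same modulators, it emits a tone-evoked
   first lick. Rewarded hits are followed by a consumption burst (12
   licks, 150 ms apart) while the valve is open. Auto-released water
   without a behavioural lick triggers no burst; this keeps offline
   reclassification of the lick stream in exact agreement with the stored
   outcomes.

**Latency law.** The tone-evoked first lick is `tone onset + X` with
`X ~ lognormal`, parameterised by its mode (`latency_mode_s − 1 s`, default
0.75 s after tone onset, i.e. 1.75 s from trial start) and a log-scale
spread (default 0.5), truncated to the trial by rejection. The law is
shifted to *tone onset* rather than trial onset: evoked responses cannot
precede the stimulus, and pre-tone licks are generated by the separate
early-lick process. Any right-skewed unimodal family would serve; the
log-normal is the two-parameter choice.

**Circadian drive.** A raised-cosine profile
`((1 + cos(2π(tod − peak)/24))/2)^sharpness`, normalised to 1 at the peak
(default 11:00, mid-dark for a 05:00–17:00 dark cycle). Sharpness 0
disables it; the default 0.4 makes the mean dark-cycle drive roughly twice
the light-cycle mean.

**Engagement oscillation.** A sinusoidal multiplier on `[1 − depth, 1]`
with period `engagement_period_h` (0 disables; 3.5 h, depth 0.8 in the
discrimination defaults), applied during the dark cycle only, to response
probabilities, spontaneous rate, and the onset rate of contact episodes —
when the cage takes a break it stops doing everything at the spout. Its
phase is drawn once per session unless pinned. The oscillator runs on
session time, so its phase is coherent across successive dark cycles; the
periodicity estimator exploits that.

## Calibration of the shipped defaults

`default_calibration()` was tuned by simulation so that a 12-cage × 7-day
detection experiment (seeds 1–12) reproduces the reference summary
statistics of such systems within their published dispersions; these are
the quantities `scripts/acceptance.R` recomputes:

| quantity | reference | simulated (seeds 1–12) |
|---|---|---|
| engaged trials / dark cycle | 54.1 ± 10.5 | 63.0 |
| engaged trials / light cycle | 13.0 ± 3.3 | 13.8 |
| rewarded trials / cage / day | ≈ 64 | 63.1 |
| dark-cycle hit rate | 6.5 ± 1.0 % | 7.00 % |
| dark-cycle early rate | 2.08 ± 1.60 % | 1.48 % |
| dark-cycle hit AULH | 79 ± 7.4 % | 82.5 % |
| latency-histogram peak | 1.75 ± 0.59 s | 1.76 s |
| water intake | ≈ 2.4 ml/mouse/day | ≈ 2.4 |

One reference figure is *not* reproduced: a trial-initiation rate of
0.07 ± 0.01 trials/min (≈ 100 trials/day). It cannot be, under the task's
own stated rules, jointly with the other anchors: because the early and
hit windows tile the trial, engaged trials = early + hit/FA trials
exactly, so the engagement and rate anchors above jointly imply ≈ 630
dark-cycle and ≈ 260 light-cycle trials per day (≈ 0.6 trials/min) — and
any cage that is ever quiet initiates a trial every ~11–20 s under the
5–9 s ITI and 5–25 s refrain rules. The simulation honestly reports its
actual ≈ 0.65–0.68 trials/min. We regard the 0.07 figure as internally
inconsistent with the other published summaries rather than as a
reproducible property of the task.

The calibration anchors fix the product of trial throughput and per-trial
response probabilities; the contact-episode means were set to produce
~650–750 dark and ~250 light trials/day, and the response probabilities
then follow from the rate anchors. Parameters were frozen after this
tuning and are not adjusted by any test.

## What the generator does and does not emulate

The virtual mouse emulates: circadian concentration of activity in the
dark; low early/false-alarm propensity with tone-locked hit latencies;
consumption bursts; cage-level (unattributed) licking; and ultradian
engagement duty cycles in discrimination. It does **not** emulate learning
dynamics across phases (habituation → shaping → detection acquisition
curves), satiety feedback of earned water on subsequent behaviour,
individual-mouse identity, sensor artefacts (missed or phantom touches),
or frequency-dependent audibility (audiogram mode draws stimuli but
response probabilities do not depend on frequency or level). Passing tests
therefore demonstrate that the analysis code recovers the generative
parameters of *this* family — rates, latencies, periods — not that it
would be robust to every artefact of a physical rig.

## Numerical and statistical choices

* **Latency histograms**: 0.1 s bins over [0, 4] s (the 30 ms sampling
  supports finer bins; 0.1 s matches usual figure granularity), counts on
  responded trials only; AULH shares computed on raw counts and averaged
  across cages for group summaries.
* **d′**: extreme proportions replaced by `1/(2n)` and `1 − 1/(2n)`; the
  latency-based variant uses the AULH shares of the hit and false-alarm
  categories as the two proportions — one reading of an under-specified
  construction, documented as such.
* **Hour-of-day bins** start on the hour, wall clock; "per day" statistics
  use calendar days from the schedule anchor and drop partial first/last
  days; cycle statistics use only complete 12 h half-cycles.
* **Periodicity**: hourly rates in complete dark cycles are linearly
  detrended per cycle, then a single sinusoid is least-squares fitted
  coherently across cycles for each candidate period (2–6 h, 0.05 h grid);
  the dominant period maximises explained variance and the strength is
  that variance fraction. Per-cycle autocorrelation at integer-hour lags
  was tried first and discarded: against binomial noise in hourly rates it
  has no power at realistic effect sizes, while the coherent fit recovers
  3–4 h periods within ±0.5 h on single-cage 7-day runs. Estimation is per
  cage — the oscillator phase is random per session, so averaging series
  across cages cancels the signal.
* **Kolmogorov–Smirnov comparisons** are two-sided with asymptotic
  p-values (`exact = FALSE`), mirroring pairwise nonparametric reporting;
  no multiple-testing correction is applied, deliberately.
* **Whitening filter**: magnitude-only inversion; the response is smoothed
  with a fractional-octave box filter (default 1/6 octave) whose window
  shrinks symmetrically near the band edges (avoiding first-order edge
  bias), and gains are `band-mean − smoothed magnitude`, so they are
  zero-mean in dB. Tone gains interpolate linearly in log-frequency.
  Smoothing trades noise immunity against exactness of the inversion: with
  zero bandwidth the grid inversion is exact, and on smooth synthetic
  responses residual ripple grows slowly with bandwidth (0.06 dB at the
  default against a 12 dB, 2-cycle ripple).
* **Problem sizes**: the reference experiment is 12 cages × 7 days
  (≈ 35 s of simulation); unit tests run single cages for one day or less.

## Known limitations

* The trials-per-minute tension described above is inherent to the
  reference anchors, not a tunable.
* Habituation logs trials with `NA` category/outcome; analysis functions
  are intended for shaping/detection/discrimination logs.
* The shaping-phase invariant "rewarded = hits + auto-rewards" holds as
  `rewarded ⇔ (hit ∨ auto)`; a trial can be both a behavioural hit and
  auto-rewarded, in which case one water delivery is counted.
* `classify_trials()` cannot recover auto-reward flags from a lick stream
  (they are not evidenced by licks); it returns `NA` there.
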