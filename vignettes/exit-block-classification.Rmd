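---
title: "Diagnosing sinoatrial exit block from beat-to-beat intervals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing sinoatrial exit block from beat-to-beat intervals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poincaregrid)
```

## The diagnostic problem

Sinus node dysfunction (SND) with sinoatrial exit block and high
parasympathetic/low sympathetic modulation (HP/LSM) both produce profound
bradycardia in dogs, often with indistinguishable 24-hour average heart
rates. The discriminating information lives in the beat-to-beat structure
of the sinus rhythm. When impulses generated inside the node intermittently
fail to conduct to the atria, the observed RR intervals accumulate whole
internal cycles: a run of blocked beats turns a ~660 ms base cycle into a
~1320 ms (2:1) or ~2640 ms (4:1) conducted interval. On a tachogram this
appears as parallel interval bands; on a Poincaré plot (each interval
against its successor) as discrete clusters off the line of identity; in
rate statistics as thousands of sinus pauses despite short prevailing
cycles. `poincaregrid` quantifies all three views and trains two
classifiers on them.

Everything operates on the RR interval as a surrogate for the sinus (PP)
interval, which presumes recordings with consistent atrioventricular
conduction and with escape beats removed. `merge_nonsinus()` implements
the removal arithmetic: intervals bounded by beats annotated non-sinus are
summed into the single sinus-to-sinus interval spanning them, so pause
counts and durations refer to the sinus node, not to whichever escape
focus happened to fire. A run of non-sinus beats at the recording tail has
no closing sinus beat; it is dropped with a warning rather than invented.

## Heart-rate variables

`basic_metrics()` reports the conventional Holter summary: average heart
rate and RR interval, pause counts strictly above 2, 3, and 4 s, longest
pause, minimum heart rate, minutes below 50 bpm, and the rate-corrected
RMSSD. Two definitions deserve comment because vendor software treats them
as black boxes:

- **Minimum heart rate** is `60000 / max(mean RR)` over a trailing 60-s
  sliding window. An instantaneous minimum would simply restate the
  longest pause; the windowed form matches how Holter reports behave.
- **Time below 50 bpm** counts whole elapsed minutes whose mean RR exceeds
  1200 ms; within a sleep window it is additionally normalised to
  minutes/hour (`sleep_metrics()`).

`crmssd()` divides the root-mean-square of successive differences by the
mean RR. The correction matters because RMSSD grows mechanically with
cycle length; the ratio is dimensionless and comparable across rates. In
SND the index is driven up not by vagal tone but by heart-rate
fragmentation — the constant multi-cycle jumps of exit block.

The stable/sleep window (`select_sleep_window()`) is chosen automatically
among contiguous whole-hour windows of 1–6 h between 22:00 and 07:00, by
summed ranks of low mean heart rate and high pause (>2 s) count, with a
penalty when the hour-to-hour coefficient of variation of mean RR exceeds
0.5 (the published procedure used visual stability; automation needs an
explicit statistic, and the threshold is exposed). Ties resolve to the
earlier start, then the longer window, making selection deterministic.

## Poincaré cluster quantification

Four measurements summarise cluster geometry: shortest and longest
interval on the line of identity (LOI, `|RR[i+1] - RR[i]| <= 40` ms by
default), their range, and the shortest horizontal deviation — the minimum
successor interval among points off the LOI band, i.e. where the plot
bifurcates away from linear rate change.

The source procedure measured these by eye, so the package must
operationalise "cluster". Points are binned at 20 ms (along x for the LOI,
along y for the deviation arm) and a bin belongs to the cluster when it
holds at least 5% of the points in the most occupied bin of its own arm
(`min_density = 0.05`, `density_reference = "modal"`). The reference to
the modal bin rather than to the total point count is deliberate: a visual
judgement responds to contrast against the bright core of the plot. In
24-hour simulations the long-interval end of the SND line of identity
carries only 2–6% of the modal density — exit block thins out consecutive
long-long interval pairs — and an absolute rule (e.g. 0.1% of all points)
would count that faint smear as cluster, hiding a real, mechanistically
meaningful asymmetry between SND and HP/LSM. Both the thresholds and the
absolute-total variant remain available, and any reported metric should
state them.

## The density-grid classifier

The classification unit is the interval triple
`(RR[i], RR[i+1], RR[i+2])` — three consecutive intervals, four QRS
complexes — extracted by a rolling window (`extract_triples()`). Training
(`train_grid()`) drops each labelled triple into a cubic cell of 60 ms
edge over a `[0, 6000)` ms domain per axis: 100^3 = 1,000,000 cells,
stored sparsely. Classification (`classify_triples()`) labels a cell with
the class of highest *normalised* density, `count / class_total`. The
normalisation is a design choice the source leaves open (raw counts,
normalised density, or recording majorities are all conceivable): raw
counts would let the most-sampled training class annex every shared cell,
which is why the raw mode survives only behind `normalize = FALSE` for
sensitivity checks. Exact ties resolve in the fixed class order BALANCED,
HPLSM, SND. Empty cells and out-of-domain triples yield `NO_DECISION`:
abstention is the grid's defining property, in contrast to the network
below.

A recording is diagnosed by the rolling appraisal (`classify_series()`):
every interval inherits the votes of the up to three triples containing it
(it is judged in first, second, and third position), takes the plurality
ignoring abstentions — the "average diagnosis" of disagreeing positions,
whose exact arithmetic the source does not specify, is here plurality with
the deterministic tie-break — and the recording's diagnosis is the class
with the largest fraction of intervals. The fractions themselves are
reported as the "relative sureness" of the decision.

## The sine-feature network

The same triples feed a deliberately small neural network: each interval
maps to `sin(2 * pi * f_k * RR)` over K = 8 dyadic frequencies (periods
75, 150, ..., 9600 ms) plus a linear `RR / 6000` term, giving 27 features;
then one ReLU hidden layer (width 64) and a linear 3-output layer trained
by gradient descent on the squared loss against one-hot targets. The
squared loss and linear output follow the stated design; no softmax is
added. The sine periods straddle the physiologic interval range so that
nearby intervals get distinguishable phases at several scales; the linear
terms make the map injective on the domain (pure sines alias) and can be
disabled (`include_linear = FALSE`) for strict sine-only behaviour.

None of the hyperparameters are stated by the source; the defaults
(lr = 0.05, 400 epochs, full-batch descent) were fixed on synthetic toy
problems — full-batch because the network is tiny and the whole training
matrix fits comfortably in memory, making minibatching pure overhead at
this scale. Training is exactly reproducible from its seed, records its
loss trajectory, and aborts (naming the epoch) if the loss turns
non-finite. Analytic gradients are verified against central finite
differences in the test suite. `predict()` always returns a class — the
network extrapolates ("guesses") where the grid abstains — and
`classify_series_nn()` applies the identical rolling-vote rule.

## The exit-block simulator

`simulate_rhythm()` implements the two-component mechanism model, which
both demonstrates that probabilistic exit block reproduces the observed
phenotypes and generates the labelled cohorts every classifier test uses.

**Internal clock.** `Tint = T0 + vtdps * vagal_tone(t) + Trand * u` with
`u ~ U[0, 1)`, `vtdps = 400` ms per vagal unit, and `Trand` equal to 40 ms
after a conducted beat or the phenotype's `Tb` after a blocked one.
"Previous beat" means the previous *internal* beat, since the randomness
term lives in the internal-interval equation.

**Vagal waveform.**
`vagal_tone(t) = 0.08 + (1/8)(1 + sin(2 pi t / 4000)) + (3/8)(1 - tanh(cos(2 pi t / P) * s))`
with P = 24 h and shape s = 1: a constant floor, a 4-s respiratory
oscillation (15 breaths/min), and a circadian wave. The published formula
is typographically corrupted in the third term; this reconstruction keeps
the stated amplitudes and the stated qualitative behaviour (a slow rise
and fall over 24 hours), and the waveform is exported (`vagal_tone()`) so
it can be inspected directly. Over 24 h it spans ~0.17–0.99.

**Exit gate.** Each internal beat is blocked with probability
`ebpsf * (vagal_tone - vth)` above `vth = 0.6`, zero below, clamped to
`[0, 1]` (the linear form exceeds 1 at high tone for ebpsf = 1.8). Blocked
beats consume their time: the conducted RR series accumulates internal
intervals across blocks, so total conducted time equals total internal
time — the conservation property the test suite asserts. A trailing
blocked run at the end of the simulated span has no closing conducted beat
and is reported only in the internal log.

Model time 0 is anchored to clock 14:00, so the circadian vagal peak
(t = 12 h) lands near 02:00 and block-rich rhythm falls inside the
2200–0700 sleep-search span — the model states no phase, and this
anchoring is the package's choice. `generate_labeled_cohort()` defaults to
one-hour recordings starting at that peak, because that is the regime in
which all three phenotypes express their characteristic patterns: below
`vth` the SND and normal presets are literally the same process.

### What the generator does and does not emulate

It reproduces: respiratory and circadian modulation of cycle length;
interval bands at integer multiples of the local base cycle; the phenotype
ordering of pauses (SND > HP/LSM > balanced), of corrected RMSSD
(SND > HP/LSM), and of Poincaré cluster compactness and early bifurcation
(SND below HP/LSM), at 24-h scale. It does not model decremental
(Wenckebach-type) sinoatrial conduction, overdrive suppression,
tachy-brady rhythms, ectopy or artifact, sympathetic surges, or the two
observed SND sub-phenotypes. Classifier results on simulated cohorts
therefore validate the pipeline's mechanics and the mechanism's
sufficiency — not clinical sensitivity on real Holter recordings, whose
rhythms are richer than the three clean processes generated here.

## Problem sizes and numerical choices

The validation suite trains on cohorts of 3 recordings per class of one
hour each (roughly 35,000 triples) and diagnoses 9 held-out recordings
with disjoint seeds; directional cohort properties are checked on 24-hour
recordings over multiple seeds, with medians across seeds guarding against
single-run flukes. These sizes keep the full suite to a few minutes while
leaving every comparison's margin wide (e.g. pauses >2 s per 24 h:
~2700 SND vs ~800 HP/LSM vs ~300 balanced; cRMSSD 0.87 vs 0.46). Grid
cells are half-open (`[0, 6000)` per axis; an interval of exactly 6000 ms
is out of domain); intervals are stored as floating-point milliseconds
with integer-exact file round trips; all stochastic paths (simulator,
network initialisation, batch shuffling) run from named integer seeds.

## Known limitations

Cluster metrics on short fixed-phase recordings are less informative than
on 24-h recordings, because the circadian sweep is what spreads the line
of identity. The sleep-window score uses end-of-interval hour attribution,
so a pause straddling an hour boundary credits the later hour. The
network's defaults favour reproducibility and speed over squeezing out the
last fraction of training loss; on the synthetic cohorts both classifiers
already agree on every held-out recording, so further tuning has nothing
to push against except real data.
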