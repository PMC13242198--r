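---
title: "Methods: simulating and analysing a pre/post tACS Posner cueing experiment"
author: "posnertacs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a pre/post tACS Posner cueing experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posnertacs)
```

## The experiment this package models

`posnertacs` implements the complete offline analysis chain of a
sham-controlled, single-blind, between-group study of transcranial
alternating current stimulation (tACS): two groups of participants perform
a Posner visuo-spatial cueing task with concurrent EEG before and after
receiving either active 40 Hz stimulation over the right parieto-occipital
region or a sham protocol. The scientific question is whether stimulation
leaves *after-effects* — changes that persist once the current is off — in
reaction times, target-evoked potentials, cue–target-interval (CTI)
oscillatory power, and long-range temporal correlations (LRTC).

Because real recordings of this kind are in-lab data that cannot be
redistributed, the package pairs every analysis stage with a synthetic-data
generator whose defaults encode the study conditions: the task structure,
the printed per-condition reaction-time distributions, and EEG signal
features (band powers, scaling exponents, component amplitudes/latencies)
with controllable pre-to-post changes. The generator is first-class, tested
code: every downstream estimator is validated by recovering the parameters
that generated its input.

## Task schedules

A session has 120 trials stratified over a 2 (cue type: endogenous arrow /
exogenous flash) × 2 (CTI: 0.5 / 1.0 s) design, 30 trials per cell, of
which exactly 24 are valid (target at the cued side) and 6 invalid. The
stratification is *exact*, not Bernoulli: the task description fixes the
proportions, and exact counts make tests deterministic; only the trial
order and cue sides are randomised. Per-trial durations are constant per
(cue type, CTI) class — 4.55, 5.05, 3.682 and 4.182 s — so the default
session always sums to 523.92 s:

```{r}
sch <- generate_schedule(seed = 1)
schedule_duration(sch)
```

Cue and fixation durations are not individually modelled; the generator
treats pre-CTI timing as opaque and aligns epochs to cue and target onsets
only, which is all the downstream analyses consume.

## Reaction-time model

Reaction times are drawn from a normal distribution truncated at zero.
Means and SDs are specified per (group, session, trial type); the defaults
are the study's sixteen printed cell statistics, which encode both the sham
group's practice effect and the larger active-group post-stimulation
speed-up that is absent in Exo-Invalid trials. A normal family is the
minimal choice consistent with reported means/SDs and non-rejected
normality screening. Two contamination processes are layered on top:
*lapses* (no response; default rate 0.018) and *fast guesses*
(anticipatory keypresses uniform on [0, 100) ms; default rate 0.035). The
default rates jointly reproduce the ~5% per-subject trial loss that the
cleaning stage removes.

Cleaning keeps responses in the closed window [0.1, 1.0] s — the rejection
rules are strictly "faster than 100 ms" and "slower than 1 s", so boundary
values are retained. All inference operates on subject-level condition
means (one value per subject × session × trial type); the mixed ANOVA's
degrees of freedom (e.g. F(1, 16) with 9 subjects per group) follow from
that choice.

## Synthetic EEG

Each trial yields two multichannel segments: a cue-aligned CTI segment
(0.5 or 1.0 s) and a target-locked segment spanning −0.1 to 0.5 s. Signals
are built additively from three components:

* **Scale-free background** with spectrum $S(f) \propto f^{-(2\alpha-1)}$
  and random phases, giving an expected detrended-fluctuation exponent of
  $\alpha$ (default 0.85, a typical resting EEG value). One continuous
  series per channel is drawn for the whole session and sliced across
  trials, rather than drawing trials independently, so that temporal
  correlations persist across concatenated CTI segments — without this the
  concatenation-mode DFA would see artificial decorrelation at segment
  boundaries.
* **Band-limited oscillations**: Gaussian noise with spectral support
  exactly on 8–12 Hz (alpha) and 30–45 Hz (gamma), scaled to an exact
  per-segment band variance (defaults 10 and 2 µV²).
* **ERP templates**: Gaussian-windowed deflections, N1 negative (default
  −3 µV at 140 ms, 18 ms width) and P3 positive (default +4 µV at 320 ms,
  45 ms width), added to target-locked segments only. The spatial profile
  is zero-mean across channels — full amplitude over the parieto-occipital
  region of interest with a small compensating counter-polarity elsewhere,
  as for a dipolar source — so that common-average re-referencing leaves
  ROI-averaged amplitudes unchanged.

Active-group post-stimulation sessions apply an `effect_spec`: alpha power
down (ratio 0.7), gamma power up (1.5), background exponent down (−0.1),
N1 more negative (−1 µV), P3 larger (+1 µV) and earlier (−15 ms). These
defaults are directionally the study's reported after-effects, at
magnitudes a parieto-occipital stimulation study would call plausible.

The default sampling rate is 256 Hz, sufficient for the 30–45 Hz gamma
band and fast for desk-scale simulation; all operations are rate-agnostic
and higher rates (e.g. a 1200 Hz laboratory rate) are supported. Rates
below 90 Hz are rejected because the gamma band would alias.

What the generator deliberately does **not** emulate: ocular/muscle
artifacts and their ICA-based removal (the cleaned-data world is assumed),
volume-conducted channel correlations, subject-level random effects in
RTs and EEG parameters, and continuous raw recordings. Passing tests
therefore demonstrate estimator correctness and pipeline calibration on
idealised signals, not robustness to real-world noise structure. In
particular, because subjects share one generating distribution per cell,
between-subject variance is smaller than in real data and simulated powers
overstate what a real n = 9 design would achieve.

## ERP quantification

Preprocessing is the fixed linear chain *common-average reference → zero-
phase low-pass → per-channel linear detrend*. The low-pass is a Hamming
windowed-sinc FIR with 30 Hz cutoff, 30→37.5 Hz transition band and ≥53 dB
stopband, applied centred after reflection padding so it adds no group
delay; only the cutoff is scientifically prescribed, the realization is a
package choice made for bit-stable, phase-neutral output. Because all
three steps are linear, the order mainly affects floating-point detail;
fixing it makes outputs reproducible to the bit.

ERPs are trial-averaged, averaged over the parieto-occipital ROI (Pz, P5,
P6, P7, P8, PO3, PO4, O1, O2) and baseline-corrected on [−0.1, 0] s.
Components are quantified over closed windows, N1 = [90, 200] ms (negative)
and P3 = [250, 400] ms (positive), by two measures:

* **Mean amplitude** — the arithmetic sample mean in the window, preferred
  over peak measures for stability.
* **Fractional-area latency (FAL)** — the waveform is rectified (absolute
  value; polarity is only a label), its cumulative trapezoidal area is
  computed, and latency is the linearly interpolated time at which the
  cumulative area reaches a fraction of the total (0.5 by default; 0.25
  and 0.75 serve as sensitivity checks).

Window membership uses nearest-sample alignment within half a sample step,
closed at both ends. The exploratory time-resolved comparison runs a
paired t-test at every time point with Benjamini–Hochberg FDR control
across time points.

## CTI band power

Each CTI segment is mean-subtracted and its power spectral density
estimated with DPSS (Slepian) multitapers. The full smoothing bandwidth is
$8 / T_{\mathrm{CTI}}$, i.e. a time-half-bandwidth product NW = 4 for
either CTI length, and only tapers with more than 90% in-band spectral
concentration are used — seven tapers under NW = 4. Tapers are computed
from the standard symmetric tridiagonal eigenproblem, with concentrations
evaluated explicitly against the sinc kernel. The PSD is the flat
(unweighted) average over retained tapers — at concentrations above 0.9,
eigenvalue weighting differs negligibly and the flat average matches the
concentration-cutoff semantics — normalised one-sided in µV²/Hz so that
the trapezoidal integral over a closed band has units of µV² and the full
integral equals the segment variance (Parseval).

One property of this estimator deserves emphasis: with NW = 4 the
smoothing kernel spans ±4 Hz at $T = 1$ s (±8 Hz at 0.5 s), which is as
wide as the alpha band itself. A narrowband process inside 8–12 Hz is
therefore smeared well outside the band, and the 8–12 Hz integral
recovers only part of its true variance (roughly half at $T = 1$ s; the
15 Hz wide gamma band loses proportionally less). This is not an
implementation artifact — the package's unit tests pin the behaviour to
the reference multitaper implementation on a pure sinusoid — but an
inherent bias of band-integrating a heavily smoothed estimate. Pre/post
*comparisons* are unaffected because the multiplicative bias cancels in
ratios and differences of the same band and segment length.

## Detrended fluctuation analysis

For a series $x(i)$, $1 \le i \le N$, the profile
$y(k) = \sum_{i=1}^{k} [x(i) - \langle x \rangle]$ is divided into
$\lfloor N/n \rfloor$ contiguous non-overlapping windows of length $n$
taken from the start of the series; each window is detrended by its
least-squares line $y_n(k)$ and

$$F(n) = \sqrt{\tfrac{1}{N'} \sum_k [y(k) - y_n(k)]^2},$$

with $N'$ the covered length (the trailing remainder of length
$N \bmod n$ is excluded and the normalisation adjusted accordingly — the
single forward pass is the simplest defensible convention where none is
prescribed). The scaling exponent $\alpha$ is the OLS slope of
$\log F(n)$ against $\log n$ over ~15 log-spaced integer window sizes in
[25, 200] samples. $\alpha = 0.5$ is uncorrelated noise, 1.5 integrated
noise; surrogates with intermediate targets are recovered within the
tolerances the test suite asserts.

A 0.5 s CTI segment at 256 Hz (128 samples) cannot support windows up to
200 samples, so the pipeline *concatenates* same-condition CTI segments
per subject and channel before analysis (the default); a per-epoch mode
that restricts the window grid and averages exponents is provided for
sensitivity checks. Concatenation is also why the generator draws one
continuous background per session.

## Inference

**Mixed ANOVA.** The 2 (group, between) × 2 (session) × 4 (trial type)
design is analysed with classical univariate mixed-model sums of squares,
computed by explicit decomposition of cell means: the between-subject
effect is tested against subjects-within-groups, and each within effect
and its group interaction against the matching
factor × subjects-within-groups stratum. Effect sizes are partial
$\eta^2 = SS_{\mathrm{eff}} / (SS_{\mathrm{eff}} + SS_{\mathrm{err}})$
with the effect's own error stratum. No sphericity correction is applied,
matching integer textbook degrees of freedom. The implementation is
cross-checked in the test suite against `stats::aov` error strata to
1e−8, and the stratum sums of squares reproduce the total exactly.

**Planned contrasts and pairwise tests.** Trial-type-specific follow-ups
compare pre-to-post change scores (Δ = post − pre) between groups with
independent t-tests, Holm-corrected across the four trial types; pairwise
pre/post and between-group comparisons use t-tests with Bonferroni
correction. Benjamini–Hochberg is used where a false-discovery-rate
criterion is stated (time-resolved ERP tests).

**Cluster-based permutation.** Sensor-space maps (band power or DFA
exponents per electrode) are compared with electrode-wise t-tests
thresholded at the two-sided p < .05 critical value; clusters are
connected components of *two or more adjacent* supra-threshold electrodes
with identical t-signs, scored by summed t. Significance is Monte Carlo
(default 2000 relabelings): within-subject sign flips for paired
contrasts, group-label shuffles for independent ones — the exchangeability
scheme follows the design of each comparison. The p-value uses the
add-one convention $(1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$ with a
conservative ≥ tie rule, so it can never be exactly zero. Electrode
adjacency is derived from a schematic 2-D 10–20 layout: electrodes closer
than 1.3× the median nearest-neighbour distance are neighbours. No
standard adjacency is prescribed for this cap, so the graph ships as a
reviewable TSV (`write_montage()`) and any user-supplied edge list can be
substituted.

**Blinding.** The post-session guess survey is evaluated with McNemar's
test with Edwards continuity correction floored at zero,
$\chi^2 = (\max(|b-c|-1, 0))^2/(b+c)$ on the discordant cells; on the
study's survey table (discordant counts 2 and 6) this gives
$\chi^2 = 9/8 = 1.125$ exactly, which is what fixes the corrected form as
the right reading.

**Sensitivity.** With n fixed at 9 per group, the design question is the
smallest standardized effect detectable at 80% power. The solver inverts
the noncentral-t power function of the two-sample test by bisection to
1e−6; at two-sided α = .05 it returns d ≈ 1.41, and at the
multiplicity-adjusted α = .0125 (0.05/4, the conservative Bonferroni
bound; a Holm-style stepwise α would be less conservative but is not
uniquely defined before seeing the data) d ≈ 1.75. A round-trip test
confirms the returned d reproduces the requested power to 1e−4.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; nothing touches the
global RNG state. The pipeline derives one named sub-stream per stage from
a single top-level seed, so `run_pipeline()` with the same configuration
produces byte-identical CSV/JSON outputs, as the test suite asserts.

The test suite exercises the estimators at desk scale chosen to keep the
default run in the low minutes while leaving Monte Carlo noise well below
the asserted tolerances: DFA calibration uses 200 replicates of
4,096–10,000-sample surrogates; multitaper calibration 100 one-second
segments; cluster-test calibration 300 null and 200 planted-effect
datasets at 500 permutations; ANOVA calibration 500 null datasets; and the
end-to-end detection check 200 simulated experiments at the full study
geometry (9 subjects per group, 120 trials per session).

## Known limitations

* Simulated subjects share one generating distribution per cell (no random
  intercepts), so simulated between-subject variance — and hence power —
  is optimistic relative to real cohorts.
* The band-integration bias of the NW = 4 multitaper (above) makes
  absolute band powers underestimates for narrow bands; comparisons and
  ratios are unaffected.
* The electrode adjacency is schematic; cluster membership near the graph
  boundary can shift under a measured cap geometry.
* DFA on concatenated CTI segments mixes within- and across-segment
  fluctuations at window sizes beyond a single segment; the generator's
  continuous background makes this consistent, but for real data the
  per-epoch mode is the more conservative choice.
* The epoch container is in-memory only; tabular artifacts (behavioural
  tables, summaries, montage/adjacency, reports) are the persistent
  interfaces.
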