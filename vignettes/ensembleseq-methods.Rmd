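---
title: "Methods: phase-locked ensemble sequence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locked ensemble sequence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ensembleseq` analyzes single-unit recordings made while an animal hunts
live prey. A hunting session decomposes into behavioral phases —
baseline (before the prey appears), introduction, chase, attack, eating
— and the package asks, per unit and per population: does the unit fire
differently in a phase than at baseline; what functional type is it;
does the population as a whole traverse a reproducible phase-locked
firing sequence; which units are optogenetically tagged members of a
genetically defined class; do a unit's spikes drive jaw-muscle (EMG)
activity; and how efficient was the hunt behaviorally.

This vignette documents the models, the tunable parameters, and the
design decisions taken where a published description leaves the
procedure under-determined. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself recompute.

## Data model

All components of a `session` share one time axis, seconds from session
start as floating point. Behavioral intervals are half-open
`[start, end)` so abutting phases never double-count a spike. Spike
times are strictly increasing per unit; the ethogram is a table of
labeled intervals plus point events (`cricket_in`, `chase_onset`,
`first_attack`, `capture`, `eating_onset`, `attack_attempt`, ...), with
the canonical event order enforced per trial. A session bundle on disk
is a JSON manifest plus delimited text files, chosen over binary
containers for diffability; unknown interval labels survive a round
trip but are ignored by the analyses.

## Per-phase responsiveness

The test statistic is the unit's mean firing rate over all intervals of
a phase. The null distribution is generated from the 60-s baseline
only, by bootstrap over its 1-s bins: each of `n_resamples` (default
1000) pseudo-windows of the phase's total duration `L` is assembled
from `floor(L)` bins drawn with replacement plus a fractional share of
one more, and each resample is additionally recentered by an
independent bootstrap draw of the baseline mean. A unit is *excited* in
a phase when its rate exceeds the 95th percentile of that distribution
and *inhibited* below the 5th.

Two alternatives were considered and rejected. Sliding (or circularly
wrapped) intact windows over the baseline preserve within-baseline rate
structure, but when `L` approaches or exceeds the 60-s baseline the
windows share most of their spikes and the null variance collapses —
in simulation, stationary Poisson units were then classified excited at
roughly 28% instead of 5%. A plain bin bootstrap fixes the window-length
scaling but still ignores that the baseline mean — the anchor the phase
rate is compared against — is itself estimated from 60 s of data; for
phases totalling 100–150 s this estimation variance dominates and
left ~13% false positives. The recentred bootstrap carries both
variance components and measures ~5–6% excited on stationary units,
which is what a 5%/95% two-sided gate should produce. The inhibited
gate mirrors the excited rule at the 5th percentile.

The phase z-score is `(phase rate − baseline mean) / baseline sd`, with
the baseline mean and sd computed from the 1-s bin rates (n−1 divisor).
A unit whose baseline bins are constant (sd = 0) has no defined z and
is excluded from the z-table, with a message. The z-vector spans five
dimensions (baseline, introduction, chase, attack, eating); the
baseline entry is identically zero by construction and is kept — it is
harmless to the SVD and keeps the geometry of the five-phase profile
explicit.

Three further criteria reuse the same machinery: head-fixed stimulus
responsiveness (any 100-ms bin of the stimulus window with |z| > 2.5
versus the baseline-window bins), risk-assessment cells (one-sided
Wilcoxon rank-sum of rates in 2-s windows after assessment onsets
against 20 windows placed uniformly at random over the session, at
p < 0.001), and velocity tuning (Pearson correlation between 0.5-s
binned rate and mean binned speed).

## Functional typing

The units × phases z-table is column-centered and decomposed by SVD;
scores are the centered data projected on the orthonormal loadings.
Centering is a deliberate default — without it the first component is
dominated by the population-mean profile rather than by the contrasts
between units — and can be disabled. Units are clustered by
complete-linkage agglomeration (Euclidean metric) on the first three
principal components, and the dendrogram is cut by count to exactly
`k` clusters, default 7. No automatic choice of `k` is attempted; the
cut criterion that produced seven types in the original analysis is not
derivable, so `k` is a user parameter and the labeling step tolerates
any `k` up to the number of archetypes.

Clusters are mapped to seven canonical archetypes by matching each
cluster's mean z-profile over (introduction, chase, attack, eating) to
sign templates that operationalize the verbal type descriptions:

| type | introduction | chase | attack | eating | reading |
|------|:---:|:---:|:---:|:---:|---------|
| I    | + | + | + | − | responds throughout, drops during eating |
| II   | · | + | ++ | − | strong attack responder, active in chase |
| III  | · | ++ | + | − | strong chase responder, sustained in attack |
| IV   | + | · | · | · | introduction only |
| V    | · | + | + | · | moderate chase/attack responder |
| VI   | · | + | · | · | chase only |
| VII  | 0 | 0 | 0 | 0 | nonresponsive |

Matching maximizes total cosine similarity under a unique (injective)
assignment, found exhaustively for up to eight clusters. The flat
template VII has no direction, so its score is `1 / (1 + ‖profile‖)`:
a near-zero cluster prefers VII over any direction template, and a
responsive cluster does not.

## Population sequence

Each behavioral phase of each trial is linearly time-warped to
`bins_per_phase` bins (default 20; five phases give a 100-bin row) so
that sessions with variable phase durations align on the four event
timepoints. Multiple chase or attack bouts within a trial are
concatenated before warping. Rows are trial-averaged, boxcar-smoothed
over 3 bins, and normalized — `"zscore"` (per-bin rate referenced to
the baseline bin statistics; the default, and the scale on which the
selectivity statistic is defined) or `"minmax"` (for heatmap display).
Whether rows should be trial-averaged or single-trial is not derivable
from the published figures; trial averaging is the default and the bin
count is a parameter.

The selectivity statistic per row is the **ridge-to-background ratio**:
the mean of the 5 bins centered on the row's peak (window truncated at
the matrix edges, mean over available bins) divided by the mean over
all bins. A flat row scores 1; a single active bin on an otherwise
silent 100-bin row scores exactly 20 (= 100/5). The per-cell null
permutes each row's bins independently (1000 shuffles), preserving the
row's value multiset while destroying temporal structure; each unit's
real ratio is paired with its mean shuffled ratio and the population is
tested by a two-sided Wilcoxon signed-rank test.

One caveat is documented rather than hidden: the ridge statistic of a
random permutation is right-skewed, so a single real draw tends to sit
*below* its shuffle mean, and the two-sided signed-rank test can
reject on completely order-free data in the negative direction. A
sequence is therefore claimed only when the median of (real − shuffled)
is positive; `sequence_significance()` reports that median alongside
the p value, and the test suite asserts the direction explicitly.

## Optogenetic tagging

A unit counts as tagged when it passes three gates: a
stimulus-associated latency rank test at p < 0.01, evoked-versus-
spontaneous mean-waveform correlation above 0.85, and per-pulse
reliability (fraction of pulses with a spike within 10 ms) above 0.6.

The latency rank test is implemented as follows. The baseline epoch is
tiled into non-overlapping 10-ms windows; consecutive windows are
grouped into sets the size of the pulse train, each set yielding a
first-spike-latency histogram over 1-ms bins plus a no-spike category;
the post-pulse windows yield the test histogram. Jensen–Shannon
divergences are computed among all histograms, each histogram is
summarized by its median divergence to the baseline sets, and
`p = (1 + #{baseline median ≥ test median}) / (G + 1)` for `G` baseline
sets. The resolution is `1/(G + 1)`: a 60-s baseline with a 50-pulse
train gives `G = 120` and a smallest attainable p of ~0.008, so the
0.01 gate is reachable and a stationary unit passes it at most ~0.8% of
the time (ties count toward the null). The 10-ms test window, the 1-ms
histogram bin, the no-spike category and the median summary are
explicit choices exposed as parameters.

Sessions carry one mean waveform per unit; evoked mean waveforms are
supplied separately (the synthetic generator stores them in the session
metadata, from where they round-trip through the manifest). A session
without waveforms errors unless the waveform gate is explicitly
skipped. Laser pulses are assumed to occupy a dedicated tagging epoch
outside the behavioral trials.

## Spike-triggered EMG

The STEMG is the mean EMG snippet in the 800-ms window around each
attack-phase spike ("normalized by the number of spikes" is read as the
mean: sum of snippets over spike count). The curve is smoothed with a
5-ms moving average, sampled on a 5-ms lag grid symmetric about zero,
and baseline-corrected by subtracting its own 100-ms boxcar-filtered
version — a constant EMG therefore yields an identically zero curve.
Spikes whose window leaves the EMG support are dropped and counted.

Significance uses surrogates that jitter every spike independently by
±100 ms uniform, preserving spike count and EMG autocorrelation while
destroying spike–EMG locking; EMG shuffling was rejected because it
whitens the trace and narrows the band artificially. The pointwise 98%
band is the 1st–99th percentile of the surrogate curves, and a
detection requires at least 5 consecutive lag-grid points above the
upper band. The published run rule ("five continuous points … in
60 ms") admits two readings — five points spanning 25 ms inside a 60-ms
search span, or a run no longer than 60 ms; both are supported through
the `search_span_s` parameter, with the former as default.

## Behavior metrics

Seven per-trial/per-session quantities are derived from the ethogram:
latency to attack (`first_attack − cricket_in`), chase rounds (chase
intervals starting before the first attack; a chase interrupted by the
prey escaping counts as its own round), attack efficiency (1 / attack
attempts before capture), attack segments (attack intervals before
capture), capture duration (`capture − first_attack`, successful trials
only), eating duration, and the session-level capture success rate in
percent. Jaw and forepaw attempts are not distinguished — an attempt is
an undifferentiated event. Failed trials (no capture before the 6-min
timeout, marked by `trial_end`) stay in the success-rate denominator
and report missing capture-dependent values; group summaries report
mean ± SEM with missing counts.

## The synthetic session generator

Because no raw recordings ship with the package, a generator emulates
exactly the structure the analyses assume, and every stage is tested
against it. Units are inhomogeneous Poisson processes with
piecewise-constant rate `baseline_rate × multiplier(phase)`; with a
piecewise-constant intensity, thinning is distributionally identical to
drawing a Poisson count per constant-rate segment and placing spikes
uniformly, which is what the generator does (exact and faster).
Baseline rates are drawn from a normal (mean 6, sd 3 spikes/s)
truncated at 0.1. The archetype multipliers over (introduction, chase,
attack, eating) are I = (3, 3, 3, 0.5), II = (1, 2, 4, 0.5),
III = (1, 4, 2, 0.5), IV = (3, 1, 1, 1), V = (1, 2, 2, 1),
VI = (1, 3, 1, 1), VII = (1, 1, 1, 1) — magnitudes are free parameters
of the generator (no per-type effect sizes in spikes/s are published),
so recovery tests state their own ground truth.

The default session: a 60-s baseline, then 5 trials of introduction
(5 s) → two chase (3 s) / attack (10 s) cycles → eating (30 s), every
duration jittered ±20%, 10-s gaps between trials; a tagging epoch of
50 laser pulses at 20 Hz (5-ms pulses) after the last trial, with
evoked spikes at 3-ms latency, 0.5-ms jitter, 0.9 reliability inserted
into 5 tagged units; a 20-Hz velocity trace elevated during the chase;
and a 1-kHz EMG trace of Gaussian noise plus a 30-ms half-sine burst
50 ms after every attack-phase spike of the coupled units (a quarter of
the units with attack multiplier > 1). A single RNG stream seeded once
from the config makes identical configs byte-identical on disk.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: within-phase rate ramps
(the statistics here are phase-resolution, so rates are flat within a
phase), refractoriness and bursting (ISI structure is exponential),
electrode drift and sorting errors, waveform variability across spikes
(one mean waveform per unit), behavioral variability beyond duration
jitter, and EMG rhythmicity (chewing is far more structured than noise
plus stereotyped bursts).

## Numerical choices and degenerate inputs

Quantiles use the R type-7 default. Peak ties resolve to the first
maximum; peak-sort ties break by unit id, so the ordering is
deterministic. The ridge window truncates at matrix edges and averages
the available bins. Rows that cannot be normalized (flat under
min–max, zero baseline sd under z-scoring) or whose background mean is
non-positive are flagged and skipped by the ratio statistic rather than
silently zeroed. Covariance estimates use the n−1 divisor and the
χ² degrees of freedom equal the feature count; singular covariances and
undersized clusters are errors, not warnings. Duplicate screening flags
a pair when more than half of the smaller train's spikes have a match
within ±1 ms, and drops the lower-count unit — the threshold is a
package decision (the published analysis states only that a
cross-correlation comparison was performed) and is configurable.

The test suite and the acceptance script run at deliberately moderate
problem sizes — e.g. 500 stationary units for classifier calibration,
280 units for typing recovery, a 300 × 100 matrix with 1000 shuffles
for the sequence statistic, 200 tagged and 400 null draws for the
tagging gates, 20 sessions per arm for the STEMG screen — chosen as the
point where the Monte Carlo error of the check is comfortably below the
margins being asserted.

## Limitations

The responsiveness test assumes a stationary baseline; slow drift
inflates its false-positive rate on real recordings. The archetype
labels are only as good as the sign templates, which encode one
reading of the published type descriptions. The sequence statistic
operates on trial-averaged, time-warped rows and cannot see
trial-to-trial sequence variability. The latency rank test's p-value
resolution is bounded by the baseline length over the pulse count. None
of the group-level hypothesis tests comparing experimental cohorts are
implemented here; the package stops at per-session quantities.
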