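# ensembleseq

Phase-locked ensemble analysis for single-unit recordings made during
naturalistic predatory hunting.

When a mouse hunts a cricket, the episode decomposes into behavioral
phases — baseline, prey introduction, chase, attack, eating — and
midbrain neurons fire in phase-locked patterns that, across the
population, form a reproducible sequence spanning the hunt. This
package implements the full analysis chain needed to establish such a
claim from spike times and an ethogram, for electrophysiologists
working with freely moving animals:

- **Per-phase responsiveness.** A unit's mean rate in phase *p*,
  `r_p`, is compared to a null distribution built by bootstrap over the
  1-s bins of the 60-s baseline (pseudo-windows of the phase's total
  duration, recentred by a bootstrap draw of the baseline mean);
  excited if `r_p` > the 95th percentile, inhibited below the 5th. The
  phase z-score is `z_p = (r_p − μ_base) / σ_base` from the same bins.
- **Functional typing.** SVD-based PCA of the units × phases z-table,
  complete-linkage hierarchical clustering on the first three PCs, cut
  to *k* = 7 clusters, and cosine matching of cluster mean profiles to
  seven canonical archetype templates (types I–VII).
- **Sequence detection.** Each phase time-warped to a fixed bin count,
  rows peak-sorted; selectivity per unit is the **ridge-to-background
  ratio** — mean of the 5 bins around the peak over the mean of all
  bins — compared against 1000 within-row shuffles with a paired
  Wilcoxon signed-rank test (a delta row of length 100 scores exactly
  100/5 = 20).
- **Optogenetic tagging.** Three gates: a stimulus-associated
  first-spike-latency rank test on Jensen–Shannon divergences of
  latency histograms (p < 0.01), evoked-vs-spontaneous waveform
  correlation (r > 0.85), and per-pulse reliability (> 0.6).
- **Spike-triggered EMG.** Mean EMG in the ±400-ms window around each
  attack-phase spike, 5-ms moving-average downsampled, baseline-
  corrected by its own 100-ms boxcar; significance = ≥ 5 consecutive
  points above a 98% band from spike-time-jittered surrogates.
- **Quality control.** ISI-violation fraction (< 1% within 2 ms),
  isolation distance (> 20), L-ratio (< 0.1), duplicate-unit screen.
- **Hunting behavior metrics.** Latency to attack, chase rounds,
  attack efficiency (1/attempts), attack segments, capture duration,
  eating duration, capture success rate.
- **Synthetic sessions.** A generator of complete sessions
  (phase-modulated Poisson units of the seven archetypes, laser-tagged
  units, spike-coupled EMG, velocity) with ground truth, so the whole
  chain is testable without any recording.

## Worked example

```r
library(ensembleseq)

pop <- simulate_population(simulation_config(seed = 42))
s   <- pop$session          # 280 units, 5 trials, laser + EMG + velocity

set.seed(42)
pr <- phase_responses(s, n_resamples = 1000)
round(100 * tapply(pr$responses$label == "excited",
                   pr$responses$phase, mean), 1)
#> introduction        chase       attack       eating
#>         33.6         72.1         60.0          3.6

ta <- label_types(cluster_types(pca_zscores(pr$zscores), n_pcs = 3, k = 7),
                  pr$zscores)
table(ta$type_label)
#>   I  II III  IV   V  VI VII
#>  25  34   3  40  10  65 103

sm  <- build_sequence_matrix(s)          # 280 x 100, 20 bins per phase
res <- sequence_significance(sm, n_shuffles = 1000)
sprintf("n = %d, signed-rank p = %.3g, median ridge excess = %.2f",
        res$n_units, res$p, res$median_diff)
#> "n = 264, signed-rank p = 4.86e-45, median ridge excess = 2.86"

tg <- identify_tagged(s)
tg$unit_id[tg$is_tagged]
#> "u107" "u158" "u170" "u174" "u227"    # exactly the 5 planted units

compute_metrics(s$ethogram)$capture_success_rate
#> 100
```

Reading the output: most units are excited in chase/attack and almost
none during eating, as the planted archetype multipliers dictate; the
population sequence is overwhelmingly significant with a positive
median ridge excess (real ratios exceed their shuffle means — the
direction that distinguishes a genuine sequence from skew artifacts);
the three tagging gates recover exactly the planted light-responsive
units. Typing on a single noisy session is imperfect by design — the
z-table route at its reference noise level is the calibrated check (see
below). Sixteen flagged/inhibited rows are excluded from the ratio
statistic (`264` of 280 usable).

A command-line wrapper with subcommands
`simulate | qc | classify | cluster | sequence | optotag | stemg |
behavior` lives at `inst/cli/ensembleseq.R`; every stochastic command
requires `--seed` and logs its parameters to `out/run.log`.

## See also

The methods vignette (`vignettes/ensembleseq-methods.Rmd`) documents
the statistical model behind every stage, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
and the design decisions taken where the published procedure is
under-determined.
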