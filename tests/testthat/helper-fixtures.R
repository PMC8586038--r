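# Shared in-code fixtures: all sessions and ethograms are built
# programmatically, no data files.

# A deterministic hand-built hunting ethogram: one baseline, `n_trials`
# trials each with one chase and one attack interval.
toy_ethogram <- function(n_trials = 2, trial_len = 60, baseline_s = 60) {
  iv <- list(data.frame(trial_id = 0L, label = "baseline",
                        start_s = 0, end_s = baseline_s))
  ev <- list()
  t0 <- baseline_s
  for (tr in seq_len(n_trials)) {
    iv[[length(iv) + 1L]] <- data.frame(
      trial_id = tr,
      label = c("introduction", "chase", "attack", "eating"),
      start_s = t0 + c(0, 5, 10, 25),
      end_s = t0 + c(5, 10, 25, 55))
    ev[[length(ev) + 1L]] <- data.frame(
      trial_id = tr,
      name = c("cricket_in", "chase_onset", "first_attack", "capture",
               "eating_onset", "trial_end"),
      time_s = t0 + c(0, 5, 10, 25, 25, 55))
    t0 <- t0 + trial_len
  }
  ethogram(do.call(rbind, iv), do.call(rbind, ev))
}

# Flat-profile (nonresponsive) archetype for null simulations.
flat_profile <- function()
  list(baseline = 1, introduction = 1, chase = 1, attack = 1, eating = 1)

# A small complete session with laser + EMG + velocity.
small_population <- function(seed = 42, n_per_type = 3) {
  counts <- stats::setNames(rep(n_per_type, 7),
                            c("I", "II", "III", "IV", "V", "VI", "VII"))
  simulate_population(simulation_config(
    n_units_per_archetype = counts, n_trials = 3, seed = seed))
}
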