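test_that("simulated ethogram has the documented trial structure", {
  set.seed(1)
  cfg <- simulation_config(n_trials = 1, cycles_per_trial = 1)
  eth <- simulate_ethogram(cfg)
  non_base <- eth$intervals[eth$intervals$label != "baseline", ]
  expect_equal(nrow(non_base), 4)  # introduction, chase, attack, eating
  expect_setequal(non_base$label,
                  c("introduction", "chase", "attack", "eating"))
  # events are constructed from the intervals
  fa <- eth$events$time_s[eth$events$name == "first_attack"]
  expect_equal(fa, non_base$start_s[non_base$label == "attack"][1])
  co <- eth$events$time_s[eth$events$name == "chase_onset"]
  expect_equal(co, min(non_base$start_s[non_base$label == "chase"]))
})

test_that("same seed gives an identical ethogram, different seed differs", {
  cfg <- simulation_config(n_trials = 3, seed = 5)
  set.seed(5); e1 <- simulate_ethogram(cfg)
  set.seed(5); e2 <- simulate_ethogram(cfg)
  set.seed(6); e3 <- simulate_ethogram(cfg)
  expect_identical(e1, e2)
  expect_false(identical(e1$intervals$end_s, e3$intervals$end_s))
})

# local oracle: direct count over intervals
count_spikes_in <- function(train, iv) {
  sum(vapply(seq_len(nrow(iv)), function(i)
    sum(train$times >= iv[i, 1] & train$times < iv[i, 2]), numeric(1)))
}

test_that("phase multipliers shape spike counts as configured", {
  eth <- toy_ethogram(n_trials = 3)
  set.seed(2)
  # multiplier 0 silences a phase completely
  pr <- list(baseline = 1, introduction = 1, chase = 0, attack = 1,
             eating = 1)
  tr <- simulate_spike_train(pr, 20, eth)
  expect_equal(count_spikes_in(tr, phase_intervals(eth, "chase")), 0)
  expect_gt(length(tr$times), 0)
})

test_that("homogeneous simulation matches the Poisson tail oracle", {
  # rate 5 spikes/s over 100 s: count must fall in the central 99.9%
  # interval of Poisson(500) in (nearly) every seeded run
  eth <- ethogram(data.frame(trial_id = 0L, label = "baseline",
                             start_s = 0, end_s = 100))
  lims <- qpois(c(5e-4, 1 - 5e-4), 500)
  set.seed(31)
  counts <- replicate(50, length(simulate_spike_train(flat_profile(), 5,
                                                      eth)$times))
  expect_true(all(counts >= lims[1] & counts <= lims[2]))
})

test_that("empirical chase/baseline rate ratio recovers the multiplier", {
  # one long chase phase vs long baseline: ratio within +/-10% at 20 Hz
  eth <- ethogram(data.frame(trial_id = c(0L, 1L),
                             label = c("baseline", "chase"),
                             start_s = c(0, 100), end_s = c(100, 200)))
  pr <- list(baseline = 1, introduction = 1, chase = 3, attack = 1,
             eating = 1)
  set.seed(4)
  tr <- simulate_spike_train(pr, 20, eth)
  r_chase <- phase_mean_rate(tr, phase_intervals(eth, "chase"))
  r_base <- phase_mean_rate(tr, phase_intervals(eth, "baseline"))
  expect_lt(abs(r_chase / r_base - 3) / 3, 0.1)
})

test_that("tagged-unit insertion follows the configured reliability", {
  span <- c(0, 100)
  base <- spike_train("u1", numeric(0), span = span)
  laser <- laser_train(seq(10, 10 + 49 / 20, by = 1 / 20))
  set.seed(9)
  # reliability 0 leaves the train untouched
  expect_identical(simulate_tagged_unit(base, laser, reliability = 0)$times,
                   base$times)
  # reliability 1, jitter 0: exactly one spike at onset + latency per pulse
  t1 <- simulate_tagged_unit(base, laser, latency_s = 0.003,
                             jitter_s = 0, reliability = 1)
  expect_equal(t1$times, laser$pulse_onsets + 0.003, tolerance = 1e-12)
  # measured reliability within the binomial 99% interval over 50 pulses
  lims <- qbinom(c(0.005, 0.995), 50, 0.7) / 50
  set.seed(10)
  hits <- replicate(20, {
    tt <- simulate_tagged_unit(base, laser, reliability = 0.7)
    reliability(tt, laser)
  })
  expect_true(all(hits >= lims[1] & hits <= lims[2]))
})

test_that("EMG coupling places bursts at the configured lag", {
  eth <- toy_ethogram(n_trials = 2)
  set.seed(12)
  tr <- simulate_spike_train(flat_profile(), 8, eth, unit_id = "c1")
  attack <- phase_intervals(eth, "attack")
  dur <- 180
  # uncoupled trace is pure noise with mean ~ 0
  set.seed(5)
  e0 <- simulate_emg(list(tr), attack, character(0), dur)
  expect_lt(abs(mean(e0$signal)), 0.005)
  # zero-amplitude bursts match the noise-only trace under the same seed
  set.seed(5)
  e1 <- simulate_emg(list(tr), attack, "c1", dur, burst_amplitude = 0)
  expect_identical(e1$signal, e0$signal)
  # cross-correlation of the coupled trace peaks within 5 ms of the lag
  set.seed(6)
  e2 <- simulate_emg(list(tr), attack, "c1", dur, lag_s = 0.05,
                     burst_amplitude = 2, noise_sd = 0.05)
  spikes_att <- tr$times[vapply(tr$times, function(t)
    any(t >= attack[, 1] & t < attack[, 2]), logical(1))]
  lags_s <- seq(0, 0.1, by = 0.001)
  xc <- vapply(lags_s, function(L) {
    idx <- round((spikes_att + L) * 1000) + 1L
    mean(abs(e2$signal[idx]))
  }, numeric(1))
  best <- lags_s[which.max(xc)]
  expect_lt(abs(best - 0.05 - 0.015), 0.02)  # burst center = lag + half width
})

test_that("population generator is deterministic and covers ground truth", {
  pop1 <- small_population(seed = 21, n_per_type = 2)
  pop2 <- small_population(seed = 21, n_per_type = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(pop1$session, d1)
  write_session(pop2$session, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)), label = f)
  gt <- pop1$ground_truth
  ids <- vapply(pop1$session$spike_trains, function(st) st$unit_id,
                character(1))
  expect_setequal(gt$unit_id, ids)
  expect_equal(anyDuplicated(gt$unit_id), 0)
  expect_equal(unname(table(gt$archetype)[c("I", "VII")]),
               c(2L, 2L), ignore_attr = TRUE)
  expect_equal(sum(gt$tagged), 5)
})

test_that("per-phase empirical rates converge to rate x multiplier", {
  # long single-phase intervals: within 5% at 1000 s
  eth <- ethogram(data.frame(trial_id = c(0L, 1L),
                             label = c("baseline", "attack"),
                             start_s = c(0, 1000), end_s = c(1000, 2000)))
  pr <- list(baseline = 1, introduction = 1, chase = 1, attack = 2.5,
             eating = 1)
  set.seed(77)
  tr <- simulate_spike_train(pr, 10, eth)
  expect_lt(abs(phase_mean_rate(tr, phase_intervals(eth, "attack")) -
                  25) / 25, 0.05)
  expect_lt(abs(phase_mean_rate(tr, phase_intervals(eth, "baseline")) -
                  10) / 10, 0.05)
})
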