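# Synthetic session generator.
#
# Emulates the statistical structure the analyses assume: per-unit
# phase-modulated Poisson firing following one of seven archetype profiles,
# a hunting ethogram of introduction -> chase/attack cycles -> eating, a
# laser tagging epoch with short-latency evoked spikes, a 1-D velocity
# trace elevated during the chase, and an EMG trace with bursts coupled to
# the attack-phase spikes of a subset of units. All functions consume the
# R global RNG; `simulate_population()` seeds it once from the config, so
# identical (config, seed) pairs give byte-identical session bundles.

#' Archetype firing-rate profiles
#'
#' Per-phase rate multipliers for the seven functional archetypes:
#' type I responds throughout introduction/chase/attack, II and V during
#' attack (II strongly, with chase activity), III and VI during chase
#' (III strongly, sustained into attack), IV only at introduction, and
#' VII is nonresponsive. The baseline multiplier is 1 by construction.
#'
#' @return data.frame with columns `type_label`, `baseline`,
#'   `introduction`, `chase`, `attack`, `eating`.
#' @export
archetype_profiles <- function() {
  data.frame(
    type_label   = c("I", "II", "III", "IV", "V", "VI", "VII"),
    baseline     = 1,
    introduction = c(3, 1, 1, 3, 1, 1, 1),
    chase        = c(3, 2, 4, 1, 2, 3, 1),
    attack       = c(3, 4, 2, 1, 2, 1, 1),
    eating       = c(0.5, 0.5, 0.5, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic session generator with the default
#' study conditions: a 60-s baseline, 5 trials of introduction (5 s) ->
#' two chase (3 s) / attack (10 s) cycles -> eating (30 s), baseline rates
#' drawn from N(6, 3) spikes/s truncated at 0.1, a 50-pulse 20-Hz tagging
#' train with 3-ms latency / 0.5-ms jitter / 0.9 reliability evoked
#' spikes, and EMG bursts lagging coupled attack spikes by +50 ms.
#'
#' @param n_units_per_archetype named integer vector (names I..VII).
#' @param baseline_rate_mean,baseline_rate_sd spikes/s of the truncated
#'   normal baseline-rate distribution (floor 0.1 spikes/s).
#' @param n_trials number of hunting trials.
#' @param phase_durations_s named numeric: mean durations of baseline,
#'   introduction, chase, attack, eating.
#' @param cycles_per_trial chase/attack cycles within each trial.
#' @param duration_jitter multiplicative half-range of the uniform jitter
#'   applied to each interval duration (0.2 means +/-20%).
#' @param capture_prob probability a trial ends in capture (failed trials
#'   stop after the last attack with no eating phase).
#' @param inter_trial_gap_s unlabeled gap between trials, seconds.
#' @param n_tagged number of optogenetically tagged units.
#' @param tag_latency_s,tag_jitter_s,tag_reliability evoked-spike latency,
#'   first-spike jitter (s) and per-pulse response probability.
#' @param n_laser_pulses,laser_hz,laser_pulse_s tagging train geometry.
#' @param emg_coupled_fraction fraction of units whose attack spikes drive
#'   EMG bursts.
#' @param emg_lag_s spike-to-burst lag, seconds.
#' @param emg_burst_amplitude,emg_noise_sd burst peak and Gaussian noise
#'   scale (EMG amplitude units).
#' @param emg_sample_rate_hz,velocity_sample_rate_hz trace sampling rates.
#' @param seed integer seed consumed once by [simulate_population()].
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_units_per_archetype = c(I = 40, II = 40,
                                                        III = 40, IV = 40,
                                                        V = 40, VI = 40,
                                                        VII = 40),
                              baseline_rate_mean = 6,
                              baseline_rate_sd = 3,
                              n_trials = 5,
                              phase_durations_s = c(baseline = 60,
                                                    introduction = 5,
                                                    chase = 3,
                                                    attack = 10,
                                                    eating = 30),
                              cycles_per_trial = 2,
                              duration_jitter = 0.2,
                              capture_prob = 1,
                              inter_trial_gap_s = 10,
                              n_tagged = 5,
                              tag_latency_s = 0.003,
                              tag_jitter_s = 0.0005,
                              tag_reliability = 0.9,
                              n_laser_pulses = 50,
                              laser_hz = 20,
                              laser_pulse_s = 0.005,
                              emg_coupled_fraction = 0.25,
                              emg_lag_s = 0.05,
                              emg_burst_amplitude = 1,
                              emg_noise_sd = 0.05,
                              emg_sample_rate_hz = 1000,
                              velocity_sample_rate_hz = 20,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$n_units_per_archetype >= 0),
            cfg$tag_reliability >= 0, cfg$tag_reliability <= 1,
            all(cfg$phase_durations_s > 0),
            cfg$emg_coupled_fraction >= 0, cfg$emg_coupled_fraction <= 1,
            cfg$capture_prob >= 0, cfg$capture_prob <= 1)
  if (!all(names(cfg$n_units_per_archetype) %in%
           archetype_profiles()$type_label))
    stop("simulation_config: archetype names must be I..VII")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a hunting ethogram
#'
#' Per trial: an introduction interval, `cycles_per_trial` alternating
#' chase/attack intervals, then (for captured trials) an eating interval.
#' Events are placed consistently with the intervals: `chase_onset` at the
#' first chase start, `first_attack` at the first attack start, `capture`
#' at the end of the last attack, plus 1 or more `attack_attempt` events
#' inside attack intervals. One baseline interval precedes trial 1.
#'
#' @param config a [simulation_config()].
#' @return an [ethogram]. Consumes the global RNG.
#' @export
simulate_ethogram <- function(config) {
  pd <- config$phase_durations_s
  jit <- function(mean_s)
    mean_s * stats::runif(1, 1 - config$duration_jitter,
                          1 + config$duration_jitter)
  iv <- list(); ev <- list()
  add_iv <- function(trial, label, s, e)
    iv[[length(iv) + 1L]] <<- data.frame(trial_id = trial, label = label,
                                         start_s = s, end_s = e)
  add_ev <- function(trial, name, t)
    ev[[length(ev) + 1L]] <<- data.frame(trial_id = trial, name = name,
                                         time_s = t)

  t <- 0
  add_iv(0L, "baseline", 0, pd[["baseline"]])
  t <- pd[["baseline"]]
  for (trial in seq_len(config$n_trials)) {
    add_ev(trial, "cricket_in", t)
    e <- t + jit(pd[["introduction"]])
    add_iv(trial, "introduction", t, e); t <- e
    captured <- stats::runif(1) < config$capture_prob
    for (cyc in seq_len(config$cycles_per_trial)) {
      if (cyc == 1L) add_ev(trial, "chase_onset", t)
      e <- t + jit(pd[["chase"]])
      add_iv(trial, "chase", t, e); t <- e
      if (cyc == 1L) add_ev(trial, "first_attack", t)
      e <- t + jit(pd[["attack"]])
      add_iv(trial, "attack", t, e)
      n_att <- 1L + stats::rpois(1, 1)
      add_ev(trial, "attack_attempt",
             sort(stats::runif(n_att, t, e - 1e-6)))
      t <- e
    }
    if (captured) {
      add_ev(trial, "capture", t)
      add_ev(trial, "eating_onset", t)
      e <- t + jit(pd[["eating"]])
      add_iv(trial, "eating", t, e); t <- e
    }
    add_ev(trial, "trial_end", t)
    t <- t + config$inter_trial_gap_s
  }
  ethogram(do.call(rbind, iv), do.call(rbind, ev))
}

# Piecewise-constant rate segments covering [0, span_end]: labeled
# intervals get baseline_rate * multiplier; unlabeled gaps fire at the
# baseline rate (multiplier 1).
rate_segments <- function(eth, span_end, multipliers) {
  iv <- eth$intervals[eth$intervals$label %in% names(multipliers), ,
                      drop = FALSE]
  iv <- iv[order(iv$start_s), , drop = FALSE]
  segs <- data.frame(start = numeric(0), end = numeric(0),
                     mult = numeric(0))
  t <- 0
  for (i in seq_len(nrow(iv))) {
    if (iv$start_s[i] > t)
      segs <- rbind(segs, data.frame(start = t, end = iv$start_s[i],
                                     mult = 1))
    segs <- rbind(segs, data.frame(start = iv$start_s[i],
                                   end = min(iv$end_s[i], span_end),
                                   mult = multipliers[[iv$label[i]]]))
    t <- min(iv$end_s[i], span_end)
    if (t >= span_end) break
  }
  if (t < span_end)
    segs <- rbind(segs, data.frame(start = t, end = span_end, mult = 1))
  segs[segs$end > segs$start, , drop = FALSE]
}

#' Simulate one phase-modulated Poisson spike train
#'
#' Inhomogeneous Poisson process with piecewise-constant rate
#' `baseline_rate * multiplier(phase at t)`; unlabeled stretches fire at
#' the baseline rate. With a piecewise-constant intensity, thinning is
#' distributionally identical to drawing a Poisson count per constant-rate
#' segment and placing the spikes uniformly, which is what is done here
#' (it is exact and faster).
#'
#' @param profile one row of [archetype_profiles()] (or any list with
#'   per-phase multiplier entries).
#' @param baseline_rate spikes/s, > 0.
#' @param eth an [ethogram].
#' @param span_end end of the simulated span, seconds (default: end of the
#'   last ethogram element).
#' @param unit_id id for the returned train.
#' @return a [spike_train]. Consumes the global RNG.
#' @export
simulate_spike_train <- function(profile, baseline_rate, eth,
                                 span_end = NULL, unit_id = "u1") {
  stopifnot(baseline_rate > 0)
  mult <- list(baseline = profile$baseline %||% 1,
               introduction = profile$introduction,
               chase = profile$chase,
               attack = profile$attack,
               eating = profile$eating)
  span_end <- span_end %||% max(eth$intervals$end_s, eth$events$time_s)
  segs <- rate_segments(eth, span_end, mult)
  times <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    lam <- baseline_rate * segs$mult[i] * (segs$end[i] - segs$start[i])
    n <- stats::rpois(1, lam)
    if (n == 0L) return(numeric(0))
    stats::runif(n, segs$start[i], segs$end[i])
  }))
  times <- sort(times)
  times <- times[!duplicated(times)]
  spike_train(unit_id, times, span = c(0, span_end))
}

#' Insert laser-evoked spikes into a train
#'
#' For a Bernoulli(`reliability`) subset of pulses, one spike is inserted
#' at `onset + latency + Normal(0, jitter)`; the result is re-sorted.
#'
#' @param train a [spike_train].
#' @param laser a [laser_train].
#' @param latency_s,jitter_s evoked-spike latency mean and sd, seconds.
#' @param reliability per-pulse response probability in `[0, 1]`.
#' @return a [spike_train]. Consumes the global RNG.
#' @export
simulate_tagged_unit <- function(train, laser, latency_s = 0.003,
                                 jitter_s = 0.0005, reliability = 0.9) {
  stopifnot(reliability >= 0, reliability <= 1)
  onsets <- laser$pulse_onsets
  respond <- stats::runif(length(onsets)) < reliability
  evoked <- onsets[respond] + latency_s +
    stats::rnorm(sum(respond), 0, jitter_s)
  times <- sort(c(train$times, evoked))
  times <- times[!duplicated(times)]
  times <- pmin(pmax(times, train$span[1]), train$span[2])
  spike_train(train$unit_id, times, span = train$span,
              waveform = train$waveform)
}

# Half-sine EMG burst kernel, `dur_s` long at `rate` Hz, unit peak.
emg_burst_kernel <- function(rate, dur_s = 0.03) {
  n <- max(2L, round(dur_s * rate))
  sin(pi * (seq_len(n) - 0.5) / n)
}

#' Simulate a spike-coupled EMG trace
#'
#' Gaussian noise plus a stereotyped half-sine burst added at
#' `spike + lag` for every attack-phase spike of the coupled units.
#'
#' @param spike_trains list of [spike_train]s.
#' @param attack_intervals two-column matrix of attack `[start, end)`
#'   bounds (e.g. `phase_intervals(eth, "attack")`).
#' @param coupled_ids character vector of coupled unit ids (may be empty).
#' @param duration_s trace duration, seconds, covering the session span.
#' @param lag_s spike-to-burst lag, seconds.
#' @param burst_amplitude burst peak amplitude.
#' @param noise_sd Gaussian noise sd.
#' @param sample_rate Hz (default 1000).
#' @return an [emg_trace]. Consumes the global RNG (noise first, so a
#'   zero-amplitude trace matches the noise-only trace under one seed).
#' @export
simulate_emg <- function(spike_trains, attack_intervals, coupled_ids,
                         duration_s, lag_s = 0.05, burst_amplitude = 1,
                         noise_sd = 0.05, sample_rate = 1000) {
  n <- ceiling(duration_s * sample_rate)
  sig <- stats::rnorm(n, 0, noise_sd)
  kern <- burst_amplitude * emg_burst_kernel(sample_rate)
  attack_intervals <- as_interval_matrix(attack_intervals)
  for (st in spike_trains) {
    if (!(st$unit_id %in% coupled_ids)) next
    keep <- rep(FALSE, length(st$times))
    for (i in seq_len(nrow(attack_intervals)))
      keep <- keep | (st$times >= attack_intervals[i, 1] &
                        st$times < attack_intervals[i, 2])
    for (t in st$times[keep]) {
      i0 <- round((t + lag_s) * sample_rate) + 1L
      idx <- i0:(i0 + length(kern) - 1L)
      ok <- idx >= 1L & idx <= n
      sig[idx[ok]] <- sig[idx[ok]] + kern[ok]
    }
  }
  emg_trace(sig, sample_rate = sample_rate, t0 = 0)
}

# Biphasic mean spike waveform (32 samples at 30 kHz): narrow negative
# trough followed by a broader positive afterwave; per-unit shape jitter.
random_waveform <- function(n_samples = 32L) {
  x <- seq_len(n_samples)
  trough <- stats::runif(1, 8, 11)
  peak <- trough + stats::runif(1, 6, 10)
  a <- stats::runif(1, 0.8, 1.5)
  b <- stats::runif(1, 0.2, 0.6)
  -a * exp(-(x - trough)^2 / stats::runif(1, 2, 5)) +
    b * exp(-(x - peak)^2 / stats::runif(1, 12, 30))
}

simulate_velocity <- function(eth, span_end, sample_rate = 20,
                              noise_sd = 1) {
  n <- ceiling(span_end * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  base <- c(baseline = 2, introduction = 4, chase = 14, attack = 6,
            eating = 1)
  speed <- rep(2, n)
  iv <- eth$intervals
  for (i in seq_len(nrow(iv))) {
    if (!iv$label[i] %in% names(base)) next
    sel <- t >= iv$start_s[i] & t < iv$end_s[i]
    speed[sel] <- base[[iv$label[i]]]
  }
  speed <- pmax(speed + stats::rnorm(n, 0, noise_sd), 0)
  velocity_trace(speed, sample_rate = sample_rate, t0 = 0)
}

#' Simulate a full session with ground truth
#'
#' Draws an ethogram, one phase-modulated Poisson train per configured
#' unit (archetype multipliers from [archetype_profiles()]), a laser
#' tagging epoch appended after the last trial with evoked spikes inserted
#' into the tagged units, per-unit mean waveforms (evoked copies stored in
#' `session$metadata$evoked_waveforms`), a velocity trace and a
#' spike-coupled EMG trace. Coupled units are drawn from units with an
#' attack multiplier > 1 (they must fire during attack for the coupling
#' to exist).
#'
#' @param config a [simulation_config()]; `config$seed` seeds the global
#'   RNG once at entry.
#' @return list with elements `session` (a validated [session]) and
#'   `ground_truth` (data.frame: `unit_id`, `archetype`, `tagged`,
#'   `emg_coupled`).
#' @export
simulate_population <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  prof <- archetype_profiles()
  eth <- simulate_ethogram(config)
  behav_end <- max(eth$intervals$end_s, eth$events$time_s)

  # dedicated tagging epoch after behavior
  laser_start <- behav_end + 20
  onsets <- laser_start + (seq_len(config$n_laser_pulses) - 1L) /
    config$laser_hz
  laser <- laser_train(onsets, pulse_duration = config$laser_pulse_s,
                       frequency = config$laser_hz)
  span_end <- max(onsets) + 1

  counts <- config$n_units_per_archetype
  arch <- rep(names(counts), counts)
  n_units <- length(arch)
  unit_ids <- sprintf("u%03d", seq_len(n_units))
  rates <- pmax(stats::rnorm(n_units, config$baseline_rate_mean,
                             config$baseline_rate_sd), 0.1)

  tagged <- rep(FALSE, n_units)
  if (config$n_tagged > 0)
    tagged[sample.int(n_units, min(config$n_tagged, n_units))] <- TRUE

  att_mult <- stats::setNames(prof$attack, prof$type_label)
  couplable <- which(att_mult[arch] > 1)
  n_coupled <- round(config$emg_coupled_fraction * length(couplable))
  coupled <- rep(FALSE, n_units)
  if (n_coupled > 0)
    coupled[sample(couplable, n_coupled)] <- TRUE

  trains <- vector("list", n_units)
  evoked_wf <- list()
  for (i in seq_len(n_units)) {
    p <- prof[prof$type_label == arch[i], ]
    tr <- simulate_spike_train(p, rates[i], eth, span_end = span_end,
                               unit_id = unit_ids[i])
    wf <- random_waveform()
    tr$waveform <- wf
    if (tagged[i])
      tr <- simulate_tagged_unit(tr, laser,
                                 latency_s = config$tag_latency_s,
                                 jitter_s = config$tag_jitter_s,
                                 reliability = config$tag_reliability)
    evoked_wf[[unit_ids[i]]] <- wf + stats::rnorm(length(wf), 0,
                                                  0.02 * max(abs(wf)))
    trains[[i]] <- tr
  }

  vel <- simulate_velocity(eth, behav_end,
                           sample_rate = config$velocity_sample_rate_hz)
  emg <- simulate_emg(trains, phase_intervals(eth, "attack"),
                      unit_ids[coupled], duration_s = span_end,
                      lag_s = config$emg_lag_s,
                      burst_amplitude = config$emg_burst_amplitude,
                      noise_sd = config$emg_noise_sd,
                      sample_rate = config$emg_sample_rate_hz)

  s <- session(trains, eth, velocity = vel, laser = laser, emg = emg,
               metadata = list(generator = "ensembleseq-synthetic",
                               seed = config$seed,
                               evoked_waveforms = evoked_wf))
  gt <- data.frame(unit_id = unit_ids, archetype = arch, tagged = tagged,
                   emg_coupled = coupled, baseline_rate = rates,
                   stringsAsFactors = FALSE)
  list(session = s, ground_truth = gt)
}

#' Simulate a phase z-score table with planted archetypes
#'
#' Direct generator for the typing stage: each unit's 5-phase z-profile is
#' its archetype's canonical profile plus i.i.d. Gaussian noise. The
#' baseline column stays 0 by construction (z is baseline-referenced).
#'
#' @param n_per_type named integer vector (names I..VII).
#' @param noise_sd z-score noise sd (default 0.3).
#' @return list: `table` (a `zscore_table`), `archetype` (character
#'   vector of planted labels). Consumes the global RNG.
#' @export
simulate_zscore_table <- function(n_per_type = c(I = 40, II = 40, III = 40,
                                                 IV = 40, V = 40, VI = 40,
                                                 VII = 40),
                                  noise_sd = 0.3) {
  profiles <- rbind(I   = c(2, 2, 2, -1),
                    II  = c(0, 1, 2, -1),
                    III = c(0, 2, 1, -1),
                    IV  = c(2, 0, 0, 0),
                    V   = c(0, 1, 1, 0),
                    VI  = c(0, 2, 0, 0),
                    VII = c(0, 0, 0, 0))
  arch <- rep(names(n_per_type), n_per_type)
  n <- length(arch)
  z <- profiles[arch, , drop = FALSE] +
    matrix(stats::rnorm(n * 4, 0, noise_sd), n, 4)
  tab <- cbind(baseline = 0, z)
  colnames(tab) <- c("baseline", "introduction", "chase", "attack",
                     "eating")
  rownames(tab) <- sprintf("u%03d", seq_len(n))
  list(table = structure(tab, class = c("zscore_table", class(tab))),
       archetype = arch)
}
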