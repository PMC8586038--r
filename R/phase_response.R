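# Per-phase responsiveness against a resampled-baseline null, phase
# z-scores, and the sensory / risk-assessment / velocity-tuning criteria.
#
# The null for a phase is built by bootstrap over the 1-s bins of the
# pre-introduction baseline: each resample assembles a pseudo-window of
# the phase's total duration from bins drawn with replacement and
# records its mean rate. A unit is excited in a phase when its phase
# rate exceeds the 95th percentile of that distribution, inhibited below
# the 5th. Resampling bins (rather than sliding intact windows over the
# baseline) keeps the null variance at the Poisson-sampling scale even
# when a phase's total duration approaches or exceeds the baseline
# length; intact windows of such lengths share most of their spikes and
# their variance collapses, which would misclassify nearly everything.
# The phase z-score references the mean and (n-1) standard deviation of
# the same 1-s bin rates.

RESPONSE_PHASES <- c("introduction", "chase", "attack", "eating")

#' Mean firing rate over a set of intervals
#'
#' @param train a [spike_train] (or bare sorted time vector).
#' @param intervals two-column matrix / list of `[start, end)` bounds with
#'   positive total duration.
#' @return spikes/s: total spikes in the intervals / total duration.
#' @export
phase_mean_rate <- function(train, intervals) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  iv <- as_interval_matrix(intervals)
  dur <- sum(iv[, 2] - iv[, 1])
  if (!is.finite(dur) || dur <= 0)
    stop("phase_mean_rate: total interval duration must be > 0")
  count_spikes(t, iv) / dur
}

#' Resampled-baseline null for one unit
#'
#' Bootstrap over the 1-s bins of the baseline interval: each of the
#' `n_resamples` pseudo-windows of length `phase_duration_s` is the sum
#' of `floor(phase_duration_s)` bins drawn with replacement plus a
#' fractional share of one more, divided by the window length. Also
#' records the baseline mean and sd of the bin rates (n-1 divisor),
#' which the z-score uses.
#'
#' @param train a [spike_train] (or bare time vector).
#' @param baseline_interval length-2 numeric `[start, end)` of the
#'   baseline, typically the 60 s before prey introduction; must cover
#'   at least 2 whole bins.
#' @param phase_duration_s pseudo-window length: the total duration of
#'   the phase being tested, seconds.
#' @param n_resamples number of pseudo-windows (default 1000, >= 100).
#' @param bin_s bin width, seconds (default 1).
#' @return object of class `baseline_null`: `resampled_rates`,
#'   `baseline_mean`, `baseline_sd`, `bin_rates` (spikes/s per bin).
#'   Consumes the global RNG.
#' @export
baseline_null <- function(train, baseline_interval, phase_duration_s,
                          n_resamples = 1000, bin_s = 1) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  b0 <- baseline_interval[1]; b1 <- baseline_interval[2]
  if (!(b1 > b0)) stop("baseline_null: empty baseline interval")
  if (n_resamples < 100) stop("baseline_null: n_resamples must be >= 100")
  if (phase_duration_s <= 0)
    stop("baseline_null: phase_duration_s must be > 0")
  nb <- floor((b1 - b0) / bin_s)
  if (nb < 2) stop("baseline_null: baseline shorter than 2 bins")
  edges <- b0 + bin_s * 0:nb
  bin_counts <- count_in_intervals(t, edges[-(nb + 1L)], edges[-1L])
  m <- floor(phase_duration_s / bin_s)
  frac <- phase_duration_s / bin_s - m
  draws <- matrix(bin_counts[sample.int(nb, n_resamples * (m + 1L),
                                        replace = TRUE)],
                  nrow = n_resamples)
  totals <- if (m > 0) rowSums(draws[, seq_len(m), drop = FALSE]) else 0
  totals <- totals + frac * draws[, m + 1L]
  # The observed baseline mean is itself an estimate; a phase rate is
  # compared to it, so the null must carry both the phase-window
  # sampling variance and the baseline-mean estimation variance. Each
  # resample therefore recenters the pseudo-window rate by an
  # independent bootstrap draw of the baseline mean.
  base_draws <- matrix(bin_counts[sample.int(nb, n_resamples * nb,
                                             replace = TRUE)],
                       nrow = n_resamples)
  base_mean_obs <- mean(bin_counts) / bin_s
  rates <- totals / phase_duration_s +
    base_mean_obs - rowMeans(base_draws) / bin_s
  structure(list(resampled_rates = rates,
                 baseline_mean = mean(bin_counts / bin_s),
                 baseline_sd = stats::sd(bin_counts / bin_s),
                 bin_rates = as.numeric(bin_counts / bin_s)),
            class = "baseline_null")
}

#' Classify a phase rate against the baseline null
#'
#' Excited when the phase mean rate exceeds the 95th percentile of the
#' resampled baseline rates, inhibited below the 5th percentile, else
#' nonresponsive.
#'
#' @param phase_rate spikes/s.
#' @param null a [baseline_null()].
#' @return one of `"excited"`, `"inhibited"`, `"nonresponsive"`.
#' @export
classify_response <- function(phase_rate, null) {
  stopifnot(inherits(null, "baseline_null"))
  q <- stats::quantile(null$resampled_rates, c(0.05, 0.95), names = FALSE)
  if (phase_rate > q[2]) "excited"
  else if (phase_rate < q[1]) "inhibited"
  else "nonresponsive"
}

#' Phase z-score
#'
#' `(phase_rate - baseline_mean) / baseline_sd` with baseline statistics
#' from 1-s bins of the baseline window (n-1 divisor).
#'
#' @inheritParams classify_response
#' @return dimensionless z.
#' @export
zscore_phase <- function(phase_rate, null) {
  stopifnot(inherits(null, "baseline_null"))
  if (!is.finite(null$baseline_sd) || null$baseline_sd <= 0)
    stop("zscore_phase: degenerate baseline (sd = 0); unit must be excluded")
  (phase_rate - null$baseline_mean) / null$baseline_sd
}

#' Per-unit phase responses for a session
#'
#' Runs the responsiveness classifier and z-score for every unit and
#' every hunting phase (introduction, chase, attack, eating) against the
#' session's baseline. Units with a degenerate baseline (sd = 0) are
#' excluded from the z-table and listed in `excluded`.
#'
#' @param s a [session] whose ethogram has a `baseline` interval and the
#'   four hunting phases.
#' @param n_resamples resamples per null (default 1000).
#' @return list: `zscores` (units x 5 matrix, class `zscore_table`;
#'   baseline column identically 0), `responses` (data.frame: `unit_id`,
#'   `phase`, `mean_rate`, `z`, `label`, `null_p05`, `null_p95`),
#'   `excluded` (unit ids). Consumes the global RNG.
#' @export
phase_responses <- function(s, n_resamples = 1000) {
  stopifnot(inherits(s, "session"))
  base_iv <- phase_intervals(s$ethogram, "baseline")
  if (nrow(base_iv) == 0L)
    stop("phase_responses: ethogram has no baseline interval")
  base_iv <- base_iv[1, ]
  phase_iv <- lapply(RESPONSE_PHASES, function(ph)
    phase_intervals(s$ethogram, ph))
  names(phase_iv) <- RESPONSE_PHASES
  for (ph in RESPONSE_PHASES)
    if (nrow(phase_iv[[ph]]) == 0L)
      stop("phase_responses: phase '", ph, "' absent from ethogram")

  rows <- list(); zrows <- list(); excluded <- character(0)
  for (st in s$spike_trains) {
    z <- stats::setNames(numeric(length(RESPONSE_PHASES)), RESPONSE_PHASES)
    unit_rows <- list()
    degenerate <- FALSE
    for (ph in RESPONSE_PHASES) {
      iv <- phase_iv[[ph]]
      dur <- sum(iv[, 2] - iv[, 1])
      rate <- phase_mean_rate(st, iv)
      null <- baseline_null(st, base_iv, dur, n_resamples)
      q <- stats::quantile(null$resampled_rates, c(0.05, 0.95),
                           names = FALSE)
      lab <- classify_response(rate, null)
      zval <- if (null$baseline_sd > 0) zscore_phase(rate, null)
      else { degenerate <- TRUE; NA_real_ }
      z[ph] <- zval
      unit_rows[[ph]] <- data.frame(unit_id = st$unit_id, phase = ph,
                                    mean_rate = rate, z = zval,
                                    label = lab, null_p05 = q[1],
                                    null_p95 = q[2],
                                    stringsAsFactors = FALSE)
    }
    rows <- c(rows, unit_rows)
    if (degenerate) excluded <- c(excluded, st$unit_id)
    else zrows[[st$unit_id]] <- c(baseline = 0, z)
  }
  ztab <- do.call(rbind, zrows)
  if (!is.null(ztab))
    ztab <- structure(ztab, class = c("zscore_table", class(ztab)))
  if (length(excluded))
    message("phase_responses: excluded ", length(excluded),
            " unit(s) with degenerate baseline: ",
            paste(excluded, collapse = ", "))
  list(zscores = ztab, responses = do.call(rbind, rows),
       excluded = excluded)
}

#' Firing-rate / movement-speed correlation
#'
#' Bins the spike train and the speed trace on a common grid and returns
#' the Pearson correlation between binned rate and mean binned speed.
#'
#' @param train a [spike_train].
#' @param velocity a [velocity_trace] overlapping the train in time.
#' @param bin_s bin width, seconds (default 0.5).
#' @return list: `r`, `p`, `n_bins`.
#' @export
velocity_tuning <- function(train, velocity, bin_s = 0.5) {
  stopifnot(inherits(velocity, "velocity_trace"))
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  v_end <- velocity$t0 + length(velocity$speed) / velocity$sample_rate
  lo <- max(velocity$t0,
            if (inherits(train, "spike_train")) train$span[1] else 0)
  hi <- min(v_end,
            if (inherits(train, "spike_train")) train$span[2] else max(t))
  n_bins <- floor((hi - lo) / bin_s)
  if (n_bins < 10) stop("velocity_tuning: need >= 10 overlapping bins")
  edges <- lo + bin_s * 0:n_bins
  rate <- count_in_intervals(t, edges[-(n_bins + 1L)], edges[-1L]) / bin_s
  vt <- velocity$t0 + (seq_along(velocity$speed) - 0.5) / velocity$sample_rate
  bin_of <- findInterval(vt, edges, left.open = FALSE,
                         rightmost.closed = FALSE)
  keep <- bin_of >= 1L & bin_of <= n_bins
  speed <- as.numeric(tapply(velocity$speed[keep], bin_of[keep], mean))
  present <- sort(unique(bin_of[keep]))
  rate <- rate[present]
  if (stats::sd(speed) == 0 || stats::sd(rate) == 0)
    stop("velocity_tuning: constant speed or constant rate")
  ct <- stats::cor.test(rate, speed, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = length(rate))
}

#' Head-fixed stimulus responsiveness
#'
#' A unit responds to a stimulus when any bin of the stimulus window has
#' a firing-rate z-score (vs the mean/sd of the baseline-window bins)
#' exceeding the threshold in absolute value.
#'
#' @param train a [spike_train] (or bare time vector).
#' @param stimulus_window,baseline_window length-2 numeric `[start, end)`.
#' @param bin_s bin width, seconds (default 0.1).
#' @param z_threshold absolute z bound (default 2.5).
#' @return logical scalar.
#' @export
stimulus_responsive <- function(train, stimulus_window, baseline_window,
                                bin_s = 0.1, z_threshold = 2.5) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  bin_counts <- function(win) {
    nb <- floor((win[2] - win[1]) / bin_s)
    if (nb < 1) stop("stimulus_responsive: window shorter than one bin")
    edges <- win[1] + bin_s * 0:nb
    count_in_intervals(t, edges[-(nb + 1L)], edges[-1L])
  }
  base <- bin_counts(baseline_window)
  if (length(base) < 2 || stats::sd(base) == 0)
    stop("stimulus_responsive: degenerate baseline (sd = 0)")
  z <- (bin_counts(stimulus_window) - mean(base)) / stats::sd(base)
  any(abs(z) > z_threshold)
}

#' Risk-assessment cell criterion
#'
#' The firing rates in the windows following assessment onsets are
#' compared (one-sided Wilcoxon rank-sum) to the rates in `n_random`
#' windows of the same length drawn uniformly from the whole session; the
#' unit is an assessment cell when assessment rates are significantly
#' higher at `alpha`.
#'
#' @param train a [spike_train] (needs its span for the random draws).
#' @param assessment_onsets numeric vector of onset times, >= 1.
#' @param window_s window length after each onset (default 2 s).
#' @param n_random number of comparison windows (default 20).
#' @param alpha significance level (default 0.001).
#' @return logical scalar. Consumes the global RNG.
#' @export
assessment_cell <- function(train, assessment_onsets, window_s = 2,
                            n_random = 20, alpha = 0.001) {
  stopifnot(inherits(train, "spike_train"),
            length(assessment_onsets) >= 1)
  span <- train$span
  if (span[2] - span[1] <= window_s)
    stop("assessment_cell: session too short for comparison windows")
  t <- train$times
  a_starts <- assessment_onsets
  r_starts <- stats::runif(n_random, span[1], span[2] - window_s)
  a_rates <- count_in_intervals(t, a_starts, a_starts + window_s) / window_s
  r_rates <- count_in_intervals(t, r_starts, r_starts + window_s) / window_s
  if (stats::sd(c(a_rates, r_rates)) == 0) return(FALSE)
  p <- stats::wilcox.test(a_rates, r_rates, alternative = "greater",
                          exact = FALSE)$p.value
  is.finite(p) && p < alpha
}
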