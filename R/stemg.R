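# Spike-triggered EMG. The STEMG is the mean EMG snippet in the 800-ms
# window around each (attack-phase) spike, 5-ms moving-average
# downsampled and baseline-corrected by subtracting its own 100-ms
# boxcar-filtered version; significance is a run-length rule against a
# pointwise band from spike-time-jittered surrogates.

# Mean EMG snippet (sample domain) around spike times; spikes whose
# window leaves the trace support are dropped.
stemg_mean_snippet <- function(spike_times, emg, half_n) {
  sr <- emg$sample_rate
  centers <- round((spike_times - emg$t0) * sr) + 1L
  ok <- centers - half_n >= 1L & centers + half_n <= length(emg$signal)
  centers <- centers[ok]
  if (!length(centers)) stop("compute_stemg: no spike window inside EMG support")
  offsets <- -half_n:half_n
  M <- matrix(emg$signal[outer(centers, offsets, `+`)],
              nrow = length(centers))
  list(mean = colMeans(M), n_used = length(centers),
       n_dropped = sum(!ok))
}

#' Spike-triggered EMG curve
#'
#' Averages the EMG in a `+/-half_window_s` window around each spike
#' (i.e. sum of snippets normalized by the spike count), smooths with a
#' `downsample_s` moving average and samples the curve on a
#' `downsample_s` lag grid, then subtracts the `baseline_boxcar_s`
#' boxcar-filtered version of the curve (baseline correction; a constant
#' EMG therefore yields an identically zero curve).
#'
#' @param spike_times numeric vector of (attack-phase) spike times,
#'   seconds; >= 1 spike with its full window inside the EMG support.
#'   Spikes too close to the trace edges are dropped and counted.
#' @param emg an [emg_trace].
#' @param half_window_s half window, seconds (default 0.4, an 800-ms
#'   window).
#' @param downsample_s moving-average width and lag spacing (default
#'   0.005).
#' @param baseline_boxcar_s boxcar width of the baseline correction
#'   (default 0.1).
#' @return object of class `stemg_curve`: `lags` (seconds, symmetric
#'   about 0), `values` (baseline-corrected), `raw` (pre-correction),
#'   `n_spikes`, `n_dropped`, and the parameters.
#' @export
compute_stemg <- function(spike_times, emg, half_window_s = 0.4,
                          downsample_s = 0.005, baseline_boxcar_s = 0.1) {
  stopifnot(inherits(emg, "emg_trace"))
  if (!length(spike_times)) stop("compute_stemg: no spikes")
  sr <- emg$sample_rate
  half_n <- round(half_window_s * sr)
  snip <- stemg_mean_snippet(sort(as.numeric(spike_times)), emg, half_n)
  step <- max(1L, round(downsample_s * sr))
  sm <- moving_average(snip$mean, step)
  keep <- seq(1L, 2L * half_n + 1L, by = step)
  raw <- sm[keep]
  lags <- (keep - half_n - 1L) / sr
  w <- round(baseline_boxcar_s / downsample_s)
  if (w %% 2L == 0L) w <- w + 1L  # symmetric boxcar
  values <- raw - moving_average(raw, w)
  structure(list(lags = lags, values = values, raw = raw,
                 n_spikes = snip$n_used, n_dropped = snip$n_dropped,
                 half_window_s = half_window_s,
                 downsample_s = downsample_s,
                 baseline_boxcar_s = baseline_boxcar_s),
            class = "stemg_curve")
}

#' STEMG significance by surrogate band and run-length rule
#'
#' Builds a pointwise `ci` band from STEMGs of spike trains uniformly
#' jittered by `+/-jitter_s` (EMG autocorrelation is preserved; only the
#' spike-EMG locking is destroyed), then flags runs of at least
#' `min_run_points` consecutive lags whose curve exceeds the upper band,
#' provided those points fit within `search_span_s`.
#'
#' @param curve the [compute_stemg()] result for the real spikes.
#' @param spike_times the same spike times.
#' @param emg the same [emg_trace].
#' @param n_surrogates surrogate count (default 1000, >= 100).
#' @param jitter_s uniform jitter half-range, seconds (default 0.1).
#' @param ci band coverage (default 0.98: 1st-99th percentiles).
#' @param min_run_points consecutive exceeding points required (default 5).
#' @param search_span_s span the run points must fit in (default 0.06).
#' @return list: `significant_runs` (list of `c(lag_start, lag_end)`),
#'   `ci_low`, `ci_high` (per lag), `exceeds` (logical per lag),
#'   `significant` (any run). Consumes the global RNG.
#' @export
stemg_significance <- function(curve, spike_times, emg,
                               n_surrogates = 1000, jitter_s = 0.1,
                               ci = 0.98, min_run_points = 5,
                               search_span_s = 0.06) {
  stopifnot(inherits(curve, "stemg_curve"))
  if (n_surrogates < 100)
    stop("stemg_significance: need >= 100 surrogates")
  spike_times <- sort(as.numeric(spike_times))
  if (!length(spike_times)) stop("stemg_significance: no spikes")
  n_lag <- length(curve$lags)
  sur <- matrix(0, n_surrogates, n_lag)
  for (k in seq_len(n_surrogates)) {
    jit <- spike_times + stats::runif(length(spike_times), -jitter_s,
                                      jitter_s)
    sur[k, ] <- compute_stemg(jit, emg,
                              half_window_s = curve$half_window_s,
                              downsample_s = curve$downsample_s,
                              baseline_boxcar_s =
                                curve$baseline_boxcar_s)$values
  }
  alpha <- (1 - ci) / 2
  ci_low <- apply(sur, 2, stats::quantile, probs = alpha, names = FALSE)
  ci_high <- apply(sur, 2, stats::quantile, probs = 1 - alpha,
                   names = FALSE)
  exceeds <- curve$values > ci_high

  runs <- list()
  r <- rle(exceeds)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  span_ok <- (min_run_points - 1L) * curve$downsample_s <= search_span_s
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= min_run_points && span_ok)
      runs[[length(runs) + 1L]] <- c(curve$lags[starts[i]],
                                     curve$lags[ends[i]])
  }
  list(significant_runs = runs, ci_low = ci_low, ci_high = ci_high,
       exceeds = exceeds, significant = length(runs) > 0)
}

#' Session-level STEMG screen
#'
#' Runs [compute_stemg()] + [stemg_significance()] per unit on that
#' unit's attack-phase spikes.
#'
#' @param s a [session] with an EMG trace.
#' @param n_surrogates,ci,min_run_points,jitter_s forwarded to
#'   [stemg_significance()].
#' @param min_spikes units with fewer attack-phase spikes are reported
#'   unscreened (default 10).
#' @return data.frame: `unit_id`, `n_spikes`, `significant`,
#'   `peak_lag_s` (lag of the curve maximum, NA if unscreened).
#' @export
stemg_screen <- function(s, n_surrogates = 1000, ci = 0.98,
                         min_run_points = 5, jitter_s = 0.1,
                         min_spikes = 10) {
  stopifnot(inherits(s, "session"))
  if (is.null(s$emg)) stop("stemg_screen: session has no EMG trace")
  attack <- phase_intervals(s$ethogram, "attack")
  out <- lapply(s$spike_trains, function(st) {
    keep <- rep(FALSE, length(st$times))
    for (i in seq_len(nrow(attack)))
      keep <- keep | (st$times >= attack[i, 1] & st$times < attack[i, 2])
    spk <- st$times[keep]
    if (length(spk) < min_spikes)
      return(data.frame(unit_id = st$unit_id, n_spikes = length(spk),
                        significant = NA, peak_lag_s = NA_real_))
    cv <- compute_stemg(spk, s$emg)
    sig <- stemg_significance(cv, spk, s$emg, n_surrogates = n_surrogates,
                              ci = ci, min_run_points = min_run_points,
                              jitter_s = jitter_s)
    data.frame(unit_id = st$unit_id, n_spikes = cv$n_spikes,
               significant = sig$significant,
               peak_lag_s = cv$lags[which.max(cv$values)])
  })
  do.call(rbind, out)
}
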