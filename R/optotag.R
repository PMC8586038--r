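# Optogenetic tag identification. A light-responsive unit must pass
# three gates: a stimulus-associated spike latency rank test (p < 0.01),
# evoked-vs-spontaneous waveform similarity (Pearson r > 0.85), and
# per-pulse response reliability (> 0.6).

# First-spike latency per window start; NA when no spike within the
# window. `times` sorted.
first_spike_latency <- function(times, starts, window_s) {
  i <- findInterval(starts, times, left.open = TRUE)  # #(t < start)
  nxt <- i + 1L
  lat <- ifelse(nxt <= length(times), times[pmin(nxt, length(times))] -
                  starts, NA_real_)
  ifelse(!is.na(lat) & lat < window_s, lat, NA_real_)
}

# Latency histogram over categories: 1-ms latency bins plus a final
# "no spike" category, normalized to a probability vector.
latency_histogram <- function(latencies, window_s, bin_s) {
  nb <- round(window_s / bin_s)
  bins <- ifelse(is.na(latencies), nb + 1L,
                 pmin(floor(latencies / bin_s) + 1L, nb))
  tabulate(bins, nbins = nb + 1L) / length(bins)
}

# Jensen-Shannon divergence between two probability vectors.
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

#' Stimulus-associated spike latency rank test
#'
#' The baseline epoch is tiled into non-overlapping windows of
#' `test_window_s`; consecutive windows are grouped into sets the size of
#' the pulse train, each set yielding a first-spike-latency histogram
#' (1-ms bins plus a no-spike category), and the post-laser windows yield
#' the test histogram. Jensen-Shannon divergences are computed between
#' all histograms, and the p value is the rank of the test histogram's
#' median divergence-to-baseline among the baseline sets' own medians:
#' `p = (1 + #(baseline median >= test median)) / (G + 1)`, with
#' resolution `1 / (G + 1)` for `G` baseline sets.
#'
#' @param train a [spike_train].
#' @param laser a [laser_train] with >= 10 pulses.
#' @param test_window_s post-pulse test window, seconds (default 0.01).
#' @param bin_s latency histogram bin, seconds (default 0.001).
#' @param baseline_epoch length-2 numeric `[start, end)` of spiking
#'   unaffected by the laser; must supply >= 20 windows.
#' @return list: `p`, `info_divergence` (the test median divergence),
#'   `n_baseline_groups`.
#' @export
salt_test <- function(train, laser, test_window_s = 0.01, bin_s = 0.001,
                      baseline_epoch) {
  t <- if (inherits(train, "spike_train")) train$times else
    sort(as.numeric(train))
  onsets <- laser$pulse_onsets
  if (length(onsets) < 10) stop("salt_test: need >= 10 laser pulses")
  b0 <- baseline_epoch[1]; b1 <- baseline_epoch[2]
  n_win <- floor((b1 - b0) / test_window_s)
  if (n_win < 20) stop("salt_test: need >= 20 baseline windows")
  win_starts <- b0 + test_window_s * (seq_len(n_win) - 1L)

  base_lat <- first_spike_latency(t, win_starts, test_window_s)
  test_lat <- first_spike_latency(t, onsets, test_window_s)
  if (all(is.na(base_lat)) && all(is.na(test_lat)))
    stop("salt_test: unit silent in every window")

  g_size <- length(onsets)
  G <- n_win %/% g_size
  if (G < 2) stop("salt_test: baseline too short for ", g_size,
                  "-window groups (need >= 2)")
  hists <- lapply(seq_len(G), function(g)
    latency_histogram(base_lat[((g - 1L) * g_size + 1L):(g * g_size)],
                      test_window_s, bin_s))
  test_hist <- latency_histogram(test_lat, test_window_s, bin_s)

  D <- matrix(0, G, G)
  for (i in seq_len(G - 1L)) for (j in (i + 1L):G)
    D[i, j] <- D[j, i] <- js_divergence(hists[[i]], hists[[j]])
  base_med <- vapply(seq_len(G), function(i)
    stats::median(D[i, -i]), numeric(1))
  test_med <- stats::median(vapply(hists, js_divergence, numeric(1),
                                   p = test_hist))
  p <- (1 + sum(base_med >= test_med)) / (G + 1)
  list(p = p, info_divergence = test_med, n_baseline_groups = G)
}

#' Evoked vs spontaneous waveform similarity
#'
#' @param evoked_mean,spontaneous_mean mean waveforms of equal length
#'   (>= 3 samples), non-constant.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
waveform_similarity <- function(evoked_mean, spontaneous_mean) {
  if (length(evoked_mean) != length(spontaneous_mean) ||
      length(evoked_mean) < 3)
    stop("waveform_similarity: waveforms must share a length >= 3")
  if (stats::sd(evoked_mean) == 0 || stats::sd(spontaneous_mean) == 0)
    stop("waveform_similarity: constant waveform")
  stats::cor(evoked_mean, spontaneous_mean)
}

#' Per-pulse response reliability
#'
#' Fraction of laser pulses followed by at least one spike within
#' `(onset, onset + window_s]`.
#'
#' @param train a [spike_train] (or bare time vector).
#' @param laser a [laser_train] with >= 1 pulse.
#' @param window_s response window, seconds (default 0.01).
#' @return fraction in `[0, 1]`.
#' @export
reliability <- function(train, laser, window_s = 0.01) {
  t <- if (inherits(train, "spike_train")) train$times else
    sort(as.numeric(train))
  onsets <- laser$pulse_onsets
  if (!length(onsets)) stop("reliability: no laser pulses")
  n_in <- findInterval(onsets + window_s, t) - findInterval(onsets, t)
  mean(n_in >= 1L)
}

#' Evoked-spike latency and jitter
#'
#' Median and standard deviation of first-spike latencies over the
#' responding pulses.
#'
#' @inheritParams reliability
#' @return list: `median_latency_s`, `jitter_s`, `n_responding`.
#' @export
latency_jitter <- function(train, laser, window_s = 0.01) {
  t <- if (inherits(train, "spike_train")) train$times else
    sort(as.numeric(train))
  lat <- first_spike_latency(t, laser$pulse_onsets, window_s)
  lat <- lat[!is.na(lat) & lat > 0]
  if (length(lat) < 2)
    stop("latency_jitter: need >= 2 responding pulses")
  list(median_latency_s = stats::median(lat), jitter_s = stats::sd(lat),
       n_responding = length(lat))
}

#' Identify optogenetically tagged units in a session
#'
#' Applies the three-gate rule per unit: latency rank test p < `p_max`,
#' evoked-vs-spontaneous waveform correlation > `r_min`, and reliability
#' > `rel_min`. The spontaneous mean waveform is the one carried by each
#' spike train; evoked mean waveforms are supplied per unit (the
#' synthetic generator stores them in `session$metadata$evoked_waveforms`).
#'
#' @param s a [session] with a laser component.
#' @param evoked_waveforms named list of evoked mean waveforms per unit
#'   id; defaults to `s$metadata$evoked_waveforms`.
#' @param baseline_epoch `[start, end)` for the latency test baseline;
#'   defaults to the ethogram's baseline interval.
#' @param window_s response window, seconds (default 0.01).
#' @param p_max,r_min,rel_min gate thresholds (0.01, 0.85, 0.6).
#' @param skip_waveform_gate when TRUE, units without waveforms are
#'   gated on the remaining two criteria (`waveform_r` reported `NA`);
#'   when FALSE (default) missing waveforms are an error.
#' @return data.frame: `unit_id`, `salt_p`, `waveform_r`, `reliability`,
#'   `median_latency_s`, `jitter_s`, `is_tagged`. Units on which the
#'   latency test is undefined (silent everywhere) get `salt_p = NA` and
#'   are not tagged.
#' @export
identify_tagged <- function(s, evoked_waveforms = NULL,
                            baseline_epoch = NULL, window_s = 0.01,
                            p_max = 0.01, r_min = 0.85, rel_min = 0.6,
                            skip_waveform_gate = FALSE) {
  stopifnot(inherits(s, "session"))
  if (is.null(s$laser)) stop("identify_tagged: session has no laser train")
  if (is.null(evoked_waveforms))
    evoked_waveforms <- s$metadata$evoked_waveforms
  if (is.null(baseline_epoch)) {
    base_iv <- phase_intervals(s$ethogram, "baseline")
    if (nrow(base_iv) == 0L)
      stop("identify_tagged: no baseline interval and no baseline_epoch")
    baseline_epoch <- base_iv[1, ]
  }
  out <- lapply(s$spike_trains, function(st) {
    id <- st$unit_id
    wr <- NA_real_
    ew <- evoked_waveforms[[id]]
    if (is.null(ew) || is.null(st$waveform)) {
      if (!skip_waveform_gate)
        stop("identify_tagged: missing waveform for unit '", id,
             "'; set skip_waveform_gate = TRUE to gate without it")
    } else wr <- waveform_similarity(ew, st$waveform)
    sp <- tryCatch(salt_test(st, s$laser, test_window_s = window_s,
                             baseline_epoch = baseline_epoch)$p,
                   error = function(e) NA_real_)
    rel <- reliability(st, s$laser, window_s)
    lj <- tryCatch(latency_jitter(st, s$laser, window_s),
                   error = function(e) list(median_latency_s = NA_real_,
                                            jitter_s = NA_real_))
    tagged <- !is.na(sp) && sp < p_max && rel > rel_min &&
      (if (is.na(wr)) skip_waveform_gate else wr > r_min)
    data.frame(unit_id = id, salt_p = sp, waveform_r = wr,
               reliability = rel,
               median_latency_s = lj$median_latency_s,
               jitter_s = lj$jitter_s, is_tagged = tagged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
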