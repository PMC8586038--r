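# Canonical data types for a recording session: spike trains, ethogram,
# velocity, laser and EMG traces, plus session bundle I/O.
#
# All components share one time axis: seconds from session start, as
# floating point. Behavioral intervals are half-open [start, end) so that
# abutting phases never double-count a spike.

PHASE_LABELS <- c("baseline", "introduction", "chase", "attack", "eating",
                  "assessment")

EVENT_NAMES <- c("cricket_in", "chase_onset", "first_attack", "capture",
                 "eating_onset", "attack_attempt", "trial_end",
                 "laser_on", "laser_off")

# Event names whose within-trial order must be monotone when all present.
ORDERED_EVENTS <- c("cricket_in", "chase_onset", "first_attack", "capture",
                    "eating_onset")

#' Construct a spike train
#'
#' A single unit's sorted spike times with the recording span and an
#' optional mean waveform (amplitude samples at the acquisition rate,
#' typically 30 kHz).
#'
#' @param unit_id character scalar identifying the unit.
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing, non-negative, all within `span`.
#' @param span length-2 numeric, recording span `(start_s, end_s)`.
#' @param waveform optional numeric vector of mean-waveform amplitudes.
#' @return an object of class `spike_train`.
#' @examples
#' spike_train("u1", c(0.1, 0.5, 2.2), span = c(0, 10))
#' @export
spike_train <- function(unit_id, times, span, waveform = NULL) {
  st <- structure(
    list(unit_id = as.character(unit_id),
         times = as.numeric(times),
         span = as.numeric(span),
         waveform = if (!is.null(waveform)) as.numeric(waveform)),
    class = "spike_train")
  validate_spike_train(st)
  st
}

validate_spike_train <- function(st) {
  if (length(st$unit_id) != 1L || is.na(st$unit_id))
    stop("spike_train: unit_id must be a single non-missing string")
  if (length(st$span) != 2L || any(!is.finite(st$span)) ||
      st$span[1] > st$span[2])
    stop("spike_train '", st$unit_id, "': span must be finite (start <= end)")
  t <- st$times
  if (length(t)) {
    if (any(!is.finite(t)))
      stop("spike_train '", st$unit_id, "': non-finite spike times")
    if (any(t < 0))
      stop("spike_train '", st$unit_id, "': negative spike times")
    if (any(diff(t) <= 0))
      stop("spike_train '", st$unit_id,
           "': spike times must be strictly increasing")
    if (t[1] < st$span[1] || t[length(t)] > st$span[2])
      stop("spike_train '", st$unit_id, "': spike times outside span")
  }
  invisible(st)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit '%s': %d spikes in [%.3f, %.3f] s%s\n",
              x$unit_id, length(x$times), x$span[1], x$span[2],
              if (is.null(x$waveform)) ""
              else sprintf(", waveform (%d samples)", length(x$waveform))))
  invisible(x)
}

#' Construct an ethogram
#'
#' A time-stamped log of labeled behavioral intervals and point events.
#' Intervals are half-open `[start_s, end_s)`; within one trial they must
#' not overlap, and the canonical hunting events, when all present, must
#' respect the order cricket_in <= chase_onset <= first_attack <= capture
#' <= eating_onset. Labels outside the canonical set are preserved but
#' ignored by the analyses.
#'
#' @param intervals data.frame with columns `trial_id`, `label`,
#'   `start_s`, `end_s`.
#' @param events data.frame with columns `trial_id`, `name`, `time_s`.
#' @return an object of class `ethogram`.
#' @export
ethogram <- function(intervals, events = NULL) {
  if (is.null(events))
    events <- data.frame(trial_id = integer(0), name = character(0),
                         time_s = numeric(0))
  intervals <- as.data.frame(intervals)[, c("trial_id", "label",
                                            "start_s", "end_s")]
  events <- as.data.frame(events)[, c("trial_id", "name", "time_s")]
  intervals$label <- as.character(intervals$label)
  events$name <- as.character(events$name)
  eth <- structure(list(intervals = intervals, events = events),
                   class = "ethogram")
  validate_ethogram(eth)
  eth
}

validate_ethogram <- function(eth) {
  iv <- eth$intervals
  if (nrow(iv)) {
    if (any(!is.finite(iv$start_s)) || any(!is.finite(iv$end_s)))
      stop("ethogram: non-finite interval bounds")
    bad <- iv$start_s >= iv$end_s
    if (any(bad))
      stop("ethogram: interval with start >= end (label '",
           iv$label[which(bad)[1]], "')")
    for (tr in unique(iv$trial_id)) {
      sub <- iv[iv$trial_id == tr, , drop = FALSE]
      o <- order(sub$start_s)
      if (any(sub$end_s[o][-nrow(sub)] > sub$start_s[o][-1] + 1e-12))
        stop("ethogram: overlapping intervals within trial ", tr)
    }
  }
  ev <- eth$events
  if (nrow(ev)) {
    if (any(!is.finite(ev$time_s)))
      stop("ethogram: non-finite event times")
    for (tr in unique(ev$trial_id)) {
      sub <- ev[ev$trial_id == tr & ev$name %in% ORDERED_EVENTS, ,
                drop = FALSE]
      # one canonical time per ordered event name; attack_attempt may repeat
      t_ord <- vapply(ORDERED_EVENTS, function(nm) {
        tt <- sub$time_s[sub$name == nm]
        if (length(tt)) min(tt) else NA_real_
      }, numeric(1))
      t_ord <- t_ord[!is.na(t_ord)]
      if (length(t_ord) > 1L && any(diff(t_ord) < -1e-12))
        stop("ethogram: events out of canonical order in trial ", tr)
    }
  }
  invisible(eth)
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %d intervals (%s), %d events, %d trial(s)\n",
              nrow(x$intervals),
              paste(unique(x$intervals$label), collapse = ", "),
              nrow(x$events),
              length(unique(c(x$intervals$trial_id, x$events$trial_id)))))
  invisible(x)
}

#' Construct a velocity trace
#'
#' @param speed numeric vector of speeds, cm/s, one per sample, >= 0.
#' @param sample_rate sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @return an object of class `velocity_trace`.
#' @export
velocity_trace <- function(speed, sample_rate, t0 = 0) {
  speed <- as.numeric(speed)
  if (any(!is.finite(speed)) || any(speed < 0))
    stop("velocity_trace: speeds must be finite and >= 0")
  if (sample_rate <= 0) stop("velocity_trace: sample_rate must be > 0")
  structure(list(speed = speed, sample_rate = sample_rate, t0 = t0),
            class = "velocity_trace")
}

#' Construct a laser pulse train
#'
#' @param pulse_onsets numeric vector of pulse onset times, seconds,
#'   strictly increasing.
#' @param pulse_duration pulse width in seconds (default 0.005, i.e. 5 ms).
#' @param frequency nominal pulse rate in Hz (informational).
#' @return an object of class `laser_train`.
#' @export
laser_train <- function(pulse_onsets, pulse_duration = 0.005,
                        frequency = NA_real_) {
  pulse_onsets <- as.numeric(pulse_onsets)
  if (length(pulse_onsets) && any(diff(pulse_onsets) <= 0))
    stop("laser_train: pulse onsets must be strictly increasing")
  if (pulse_duration <= 0) stop("laser_train: pulse_duration must be > 0")
  structure(list(pulse_onsets = pulse_onsets,
                 pulse_duration = pulse_duration,
                 frequency = frequency),
            class = "laser_train")
}

#' Construct an EMG trace
#'
#' @param signal numeric vector of EMG amplitudes (already band-passed).
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param t0 time of the first sample, seconds.
#' @return an object of class `emg_trace`.
#' @export
emg_trace <- function(signal, sample_rate = 1000, t0 = 0) {
  signal <- as.numeric(signal)
  if (any(!is.finite(signal))) stop("emg_trace: non-finite samples")
  if (sample_rate <= 0) stop("emg_trace: sample_rate must be > 0")
  structure(list(signal = signal, sample_rate = sample_rate, t0 = t0),
            class = "emg_trace")
}

#' Construct a session
#'
#' Binds spike trains, an ethogram and optional velocity, laser and EMG
#' components on one shared time axis (seconds from session start).
#'
#' @param spike_trains list of [spike_train] objects with distinct unit ids.
#' @param ethogram an [ethogram].
#' @param velocity optional [velocity_trace].
#' @param laser optional [laser_train].
#' @param emg optional [emg_trace].
#' @param metadata free-form named list (serialized to the manifest).
#' @return an object of class `session`.
#' @export
session <- function(spike_trains, ethogram, velocity = NULL, laser = NULL,
                    emg = NULL, metadata = list()) {
  s <- structure(list(spike_trains = spike_trains, ethogram = ethogram,
                      velocity = velocity, laser = laser, emg = emg,
                      metadata = metadata),
                 class = "session")
  validate_session(s)
  s
}

validate_session <- function(s) {
  if (!inherits(s$ethogram, "ethogram")) stop("session: ethogram required")
  validate_ethogram(s$ethogram)
  ids <- vapply(s$spike_trains, function(st) st$unit_id, character(1))
  if (anyDuplicated(ids))
    stop("session: duplicated unit ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  wf_len <- unique(vapply(s$spike_trains, function(st)
    length(st$waveform %||% numeric(0)), integer(1)))
  wf_len <- setdiff(wf_len, 0L)
  if (length(wf_len) > 1L)
    stop("session: waveforms must share one length across units")
  for (st in s$spike_trains) validate_spike_train(st)
  classes <- c(velocity = "velocity_trace", laser = "laser_train",
               emg = "emg_trace")
  for (nm in names(classes)) {
    if (!is.null(s[[nm]]) && !inherits(s[[nm]], classes[[nm]]))
      stop("session: '", nm, "' must be a ", classes[[nm]])
  }
  invisible(s)
}

#' @export
print.session <- function(x, ...) {
  extras <- c(if (!is.null(x$velocity)) "velocity",
              if (!is.null(x$laser)) "laser",
              if (!is.null(x$emg)) "EMG")
  cat(sprintf("<session> %d unit(s)%s\n", length(x$spike_trains),
              if (length(extras)) paste0(" + ",
                                         paste(extras, collapse = ", "))
              else ""))
  print(x$ethogram)
  invisible(x)
}

#' Intervals of one behavioral phase
#'
#' Returns the stored `[start, end)` intervals carrying a given label, in
#' time order, across all trials. An absent (but known) label yields an
#' empty result; an unknown label is an error.
#'
#' @param eth an [ethogram].
#' @param label phase label, one of the canonical labels
#'   (baseline, introduction, chase, attack, eating, assessment,
#'   `stimulus:<name>`) or any label present in the ethogram.
#' @return two-column matrix (`start_s`, `end_s`), zero rows if absent.
#' @export
phase_intervals <- function(eth, label) {
  stopifnot(inherits(eth, "ethogram"))
  known <- c(PHASE_LABELS, unique(eth$intervals$label))
  if (!(label %in% known) && !startsWith(label, "stimulus:"))
    stop("phase_intervals: unknown phase label '", label, "'")
  iv <- eth$intervals[eth$intervals$label == label, , drop = FALSE]
  iv <- iv[order(iv$start_s), , drop = FALSE]
  m <- cbind(start_s = iv$start_s, end_s = iv$end_s)
  rownames(m) <- NULL
  m
}

#' Session end time
#'
#' Latest time touched by any component, used as the simulation/analysis
#' span when no explicit span is given.
#' @param s a [session].
#' @return numeric scalar, seconds.
#' @export
session_end <- function(s) {
  ends <- c(vapply(s$spike_trains, function(st) st$span[2], numeric(1)),
            s$ethogram$intervals$end_s, s$ethogram$events$time_s)
  if (!is.null(s$laser))
    ends <- c(ends, max(s$laser$pulse_onsets, 0) + s$laser$pulse_duration)
  if (!is.null(s$emg))
    ends <- c(ends, s$emg$t0 + length(s$emg$signal) / s$emg$sample_rate)
  if (!is.null(s$velocity))
    ends <- c(ends,
              s$velocity$t0 + length(s$velocity$speed) / s$velocity$sample_rate)
  max(ends, 0)
}

# ---- session bundle I/O ----------------------------------------------------
#
# A session is stored as a directory holding a JSON manifest plus delimited
# text component files:
#   manifest.json               paths, spans, sample rates, metadata
#   spikes.csv                  unit_id, time_s
#   waveforms.csv               unit_id, sample_index, amplitude
#   ethogram.tsv                trial_id, label, start_s, end_s  (BED-like)
#   events.csv                  trial_id, name, time_s
#   velocity.csv                time_s, speed_cm_s
#   emg.csv                     time_s, amplitude
#   laser.csv                   onset_s, duration_s
# Optional components absent from the session are omitted from the bundle.

#' Write a session bundle
#'
#' @param s a validated [session].
#' @param dir target directory (created if missing).
#' @return path of the written `manifest.json`, invisibly usable with
#'   [load_session()].
#' @export
write_session <- function(s, dir) {
  validate_session(s)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("write_session: cannot create directory ", dir)

  num <- function(x) formatC(x, digits = 15, format = "g")
  wcsv <- function(df, file) utils::write.csv(df, file.path(dir, file),
                                              row.names = FALSE, quote = FALSE)

  spikes <- do.call(rbind, lapply(s$spike_trains, function(st)
    if (length(st$times))
      data.frame(unit_id = st$unit_id, time_s = num(st$times))
    else NULL))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), time_s = character(0))
  wcsv(spikes, "spikes.csv")

  manifest <- list(
    format = "ensembleseq-session/1",
    components = list(spikes = "spikes.csv", ethogram = "ethogram.tsv",
                      events = "events.csv"),
    units = lapply(s$spike_trains, function(st)
      list(unit_id = st$unit_id, span = st$span)),
    metadata = s$metadata)

  wf <- do.call(rbind, lapply(s$spike_trains, function(st)
    if (!is.null(st$waveform))
      data.frame(unit_id = st$unit_id,
                 sample_index = seq_along(st$waveform),
                 amplitude = num(st$waveform))
    else NULL))
  if (!is.null(wf)) {
    wcsv(wf, "waveforms.csv")
    manifest$components$waveforms <- "waveforms.csv"
  }

  iv <- s$ethogram$intervals
  utils::write.table(
    data.frame(trial_id = iv$trial_id, label = iv$label,
               start_s = num(iv$start_s), end_s = num(iv$end_s)),
    file.path(dir, "ethogram.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  ev <- s$ethogram$events
  wcsv(data.frame(trial_id = ev$trial_id, name = ev$name,
                  time_s = num(ev$time_s)), "events.csv")

  if (!is.null(s$velocity)) {
    v <- s$velocity
    t <- v$t0 + (seq_along(v$speed) - 1L) / v$sample_rate
    wcsv(data.frame(time_s = num(t), speed_cm_s = num(v$speed)),
         "velocity.csv")
    manifest$components$velocity <- "velocity.csv"
    manifest$velocity <- list(sample_rate = v$sample_rate, t0 = v$t0)
  }
  if (!is.null(s$emg)) {
    e <- s$emg
    t <- e$t0 + (seq_along(e$signal) - 1L) / e$sample_rate
    wcsv(data.frame(time_s = num(t), amplitude = num(e$signal)), "emg.csv")
    manifest$components$emg <- "emg.csv"
    manifest$emg <- list(sample_rate = e$sample_rate, t0 = e$t0)
  }
  if (!is.null(s$laser)) {
    l <- s$laser
    wcsv(data.frame(onset_s = num(l$pulse_onsets),
                    duration_s = num(rep(l$pulse_duration,
                                         length(l$pulse_onsets)))),
         "laser.csv")
    manifest$components$laser <- "laser.csv"
    manifest$laser <- list(pulse_duration = l$pulse_duration,
                           frequency = l$frequency)
  }

  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest_path
}

#' Load a session bundle
#'
#' Reads the bundle written by [write_session()] and re-validates every
#' invariant; a bundle violating one (unsorted spike times, overlapping
#' same-trial intervals, ...) is rejected with an error naming the culprit.
#'
#' @param manifest_path path to a `manifest.json`, or to the directory
#'   containing it.
#' @return a validated [session].
#' @export
load_session <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.json")
  if (!file.exists(manifest_path))
    stop("load_session: manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  comp <- man$components
  need <- function(name) {
    p <- file.path(dir, comp[[name]])
    if (!file.exists(p)) stop("load_session: missing component file ", p)
    p
  }

  spikes <- utils::read.csv(need("spikes"),
                            colClasses = c("character", "numeric"))
  wf <- NULL
  if (!is.null(comp$waveforms))
    wf <- utils::read.csv(need("waveforms"),
                          colClasses = c("character", "integer", "numeric"))

  trains <- lapply(man$units, function(u) {
    t <- spikes$time_s[spikes$unit_id == u$unit_id]
    w <- if (!is.null(wf)) {
      a <- wf$amplitude[wf$unit_id == u$unit_id]
      if (length(a)) a else NULL
    }
    spike_train(u$unit_id, t, span = unlist(u$span), waveform = w)
  })

  iv <- utils::read.delim(need("ethogram"),
                          colClasses = c(trial_id = "integer",
                                         label = "character",
                                         start_s = "numeric",
                                         end_s = "numeric"))
  ev <- utils::read.csv(need("events"),
                        colClasses = c(trial_id = "integer",
                                       name = "character",
                                       time_s = "numeric"))
  eth <- ethogram(iv, ev)

  vel <- NULL
  if (!is.null(comp$velocity)) {
    vdf <- utils::read.csv(need("velocity"))
    vel <- velocity_trace(vdf$speed_cm_s, man$velocity$sample_rate,
                          man$velocity$t0)
  }
  emg <- NULL
  if (!is.null(comp$emg)) {
    edf <- utils::read.csv(need("emg"))
    emg <- emg_trace(edf$amplitude, man$emg$sample_rate, man$emg$t0)
  }
  las <- NULL
  if (!is.null(comp$laser)) {
    ldf <- utils::read.csv(need("laser"))
    las <- laser_train(ldf$onset_s, man$laser$pulse_duration,
                       man$laser$frequency %||% NA_real_)
  }

  meta <- man$metadata %||% list()
  # JSON turns numeric vectors into lists of scalars; restore vectors
  meta <- rapply(meta, how = "replace", function(x) x)
  session(trains, eth, velocity = vel, laser = las, emg = emg,
          metadata = simplify_metadata(meta))
}

simplify_metadata <- function(m) {
  if (!is.list(m)) return(m)
  if (length(m) && all(!vapply(m, is.list, logical(1))) &&
      is.null(names(m)) &&
      all(vapply(m, is.numeric, logical(1))))
    return(unlist(m))
  lapply(m, simplify_metadata)
}
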