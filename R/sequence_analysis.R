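# Population sequence analysis: time-warped activity matrix, peak
# sorting, per-cell shuffle null, and the ridge-to-background statistic.
#
# Every behavioral phase is linearly rescaled ("time-warped") to a fixed
# number of bins so sessions with variable phase durations align on the
# four event timepoints (cricket in, chase onset, first attack, eating
# onset); trials are averaged and each row smoothed, then normalized.

SEQUENCE_PHASES <- c("baseline", "introduction", "chase", "attack",
                     "eating")

# Spike counts in `nbins` equal bins of the concatenated (gap-removed)
# time axis of a set of [start, end) intervals.
warp_bin_counts <- function(times, intervals, nbins) {
  iv <- as_interval_matrix(intervals)
  durs <- iv[, 2] - iv[, 1]
  cum <- c(0, cumsum(durs))
  total <- cum[length(cum)]
  conc <- numeric(0)
  for (i in seq_len(nrow(iv))) {
    sel <- times >= iv[i, 1] & times < iv[i, 2]
    conc <- c(conc, cum[i] + times[sel] - iv[i, 1])
  }
  edges <- seq(0, total, length.out = nbins + 1L)
  counts <- count_in_intervals(sort(conc), edges[-(nbins + 1L)],
                               edges[-1L])
  list(counts = counts, bin_dur = total / nbins)
}

#' Build the time-warped population sequence matrix
#'
#' For each unit and trial, the five phases (baseline, introduction,
#' chase, attack, eating) are each rescaled to `bins_per_phase` bins of
#' the phase's concatenated time (multiple chase/attack intervals within
#' a trial are concatenated before warping), rates are averaged across
#' trials, boxcar-smoothed, and per-row normalized. The shared baseline
#' interval contributes the same bins to every trial.
#'
#' @param s a [session] whose ethogram has all five phases.
#' @param bins_per_phase bins per phase (default 20; the matrix has
#'   `5 * bins_per_phase` columns).
#' @param smooth_bins boxcar width in bins (default 3).
#' @param normalize `"zscore"` (per-bin rate referenced to the 1-s-binned
#'   baseline mean/sd; the figure-style statistic), `"minmax"` (row
#'   scaled to `[0, 1]`; for display), or `"rate"` (raw spikes/s).
#' @return object of class `sequence_matrix`: `values` (units x bins),
#'   `boundaries` (bin index before which cricket_in / chase_onset /
#'   first_attack / eating_onset fall, i.e. `bins_per_phase * 1:4`),
#'   `bins_per_phase`, `phases`, `flagged` (unit ids whose row is
#'   degenerate: flat under min-max, or zero baseline sd under z-score),
#'   `normalize`.
#' @export
build_sequence_matrix <- function(s, bins_per_phase = 20, smooth_bins = 3,
                                  normalize = c("zscore", "minmax",
                                                "rate")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(s, "session"), bins_per_phase >= 1)
  eth <- s$ethogram
  iv_by_phase <- lapply(SEQUENCE_PHASES, function(ph)
    phase_intervals(eth, ph))
  names(iv_by_phase) <- SEQUENCE_PHASES
  for (ph in SEQUENCE_PHASES)
    if (nrow(iv_by_phase[[ph]]) == 0L)
      stop("build_sequence_matrix: phase '", ph, "' missing from ethogram")

  trials <- sort(unique(eth$intervals$trial_id[eth$intervals$label %in%
                                                 SEQUENCE_PHASES[-1]]))
  base_iv <- iv_by_phase$baseline[1, , drop = FALSE]
  B <- 5L * bins_per_phase

  rows <- matrix(0, length(s$spike_trains), B)
  rownames(rows) <- vapply(s$spike_trains, function(st) st$unit_id,
                           character(1))
  flagged <- character(0)
  for (u in seq_along(s$spike_trains)) {
    st <- s$spike_trains[[u]]
    acc <- matrix(0, 0, B)
    for (tr in trials) {
      tr_iv <- eth$intervals[eth$intervals$trial_id == tr, , drop = FALSE]
      per_phase <- lapply(SEQUENCE_PHASES, function(ph) {
        if (ph == "baseline") return(base_iv)
        sub <- tr_iv[tr_iv$label == ph, , drop = FALSE]
        if (nrow(sub) == 0L) return(NULL)
        cbind(sub$start_s, sub$end_s)
      })
      if (any(vapply(per_phase, is.null, logical(1)))) next
      rates <- unlist(lapply(per_phase, function(ivm) {
        wb <- warp_bin_counts(st$times, ivm, bins_per_phase)
        wb$counts / wb$bin_dur
      }))
      acc <- rbind(acc, rates)
    }
    if (nrow(acc) == 0L)
      stop("build_sequence_matrix: no complete trial found")
    row <- moving_average(colMeans(acc), smooth_bins)
    if (normalize == "minmax") {
      rng <- range(row)
      if (diff(rng) <= 0) {
        flagged <- c(flagged, st$unit_id)
      } else row <- (row - rng[1]) / diff(rng)
    } else if (normalize == "zscore") {
      nb <- floor(base_iv[1, 2] - base_iv[1, 1])
      edges <- base_iv[1, 1] + 0:nb
      bin_rates <- count_in_intervals(st$times, edges[-(nb + 1L)],
                                      edges[-1L])
      sdv <- stats::sd(bin_rates)
      if (!is.finite(sdv) || sdv <= 0) {
        flagged <- c(flagged, st$unit_id)
      } else row <- (row - mean(bin_rates)) / sdv
    }
    rows[u, ] <- row
  }
  structure(list(values = rows,
                 boundaries = bins_per_phase * 1:4,
                 bins_per_phase = bins_per_phase,
                 phases = SEQUENCE_PHASES,
                 flagged = flagged,
                 normalize = normalize),
            class = "sequence_matrix")
}

#' Sort units by peak position
#'
#' Row order of ascending argmax bin; ties broken by unit id so the sort
#' is deterministic.
#'
#' @param mat a [build_sequence_matrix()] result (or bare matrix).
#' @return integer permutation of the rows.
#' @export
peak_sort <- function(mat) {
  V <- if (inherits(mat, "sequence_matrix")) mat$values else as.matrix(mat)
  peaks <- apply(V, 1, which.max)
  ids <- rownames(V) %||% as.character(seq_len(nrow(V)))
  order(peaks, ids)
}

#' Shuffle each row of a sequence matrix
#'
#' Independently permutes the bin values within every row (the per-cell
#' shuffle null): row value multisets are preserved, temporal structure
#' is destroyed.
#'
#' @param mat a `sequence_matrix` or bare matrix.
#' @return object of the same type with shuffled values. Consumes the
#'   global RNG.
#' @export
shuffle_matrix <- function(mat) {
  is_sm <- inherits(mat, "sequence_matrix")
  V <- if (is_sm) mat$values else as.matrix(mat)
  V2 <- V
  for (i in seq_len(nrow(V)))
    V2[i, ] <- V[i, sample.int(ncol(V))]
  if (is_sm) { mat$values <- V2; mat } else V2
}

#' Ridge-to-background ratio of one activity row
#'
#' Mean of the 5 bins surrounding the row's peak (window truncated at the
#' edges, mean over the available bins) divided by the mean over all
#' bins: a selectivity statistic — a flat row gives 1, a single spike of
#' activity on an empty background of length N gives N/5.
#'
#' @param row numeric vector, length >= 5, with positive mean.
#' @param window ridge width in bins (default 5).
#' @return ratio > 0.
#' @export
ridge_to_background <- function(row, window = 5) {
  row <- as.numeric(row)
  n <- length(row)
  if (n < window) stop("ridge_to_background: row shorter than the window")
  bg <- mean(row)
  if (!is.finite(bg) || bg <= 0)
    stop("ridge_to_background: background mean must be > 0")
  p <- which.max(row)
  half <- (window - 1L) %/% 2L
  w <- max(1L, p - half):min(n, p + half)
  mean(row[w]) / bg
}

#' Shuffle-controlled sequence significance
#'
#' Compares each unit's real ridge-to-background ratio to its mean ratio
#' over `n_shuffles` within-row permutations, with a paired two-sided
#' Wilcoxon signed-rank test across units. Flagged rows and rows with a
#' non-positive background are skipped.
#'
#' @param mat a [build_sequence_matrix()] result (or bare matrix).
#' @param n_shuffles permutations per row (default 1000, >= 1).
#' @return list: `ratios` (data.frame `unit_id`, `real`, `shuffled`),
#'   `p` (signed-rank p), `median_diff` (median of real minus shuffled;
#'   a sequence requires this to be positive, see Details comment in
#'   the source), `n_units`, `skipped` (unit ids). Consumes the global
#'   RNG.
#' @export
sequence_significance <- function(mat, n_shuffles = 1000) {
  if (n_shuffles < 1) stop("sequence_significance: n_shuffles must be >= 1")
  is_sm <- inherits(mat, "sequence_matrix")
  V <- if (is_sm) mat$values else as.matrix(mat)
  ids <- rownames(V) %||% as.character(seq_len(nrow(V)))
  flagged <- if (is_sm) mat$flagged else character(0)
  usable <- logical(nrow(V))
  for (i in seq_len(nrow(V)))
    usable[i] <- !(ids[i] %in% flagged) && mean(V[i, ]) > 0
  if (sum(usable) < 10)
    stop("sequence_significance: need >= 10 usable rows")

  real <- shuf <- rep(NA_real_, nrow(V))
  for (i in which(usable)) {
    r <- V[i, ]
    real[i] <- ridge_to_background(r)
    acc <- 0
    for (k in seq_len(n_shuffles))
      acc <- acc + ridge_to_background(r[sample.int(length(r))])
    shuf[i] <- acc / n_shuffles
  }
  keep <- which(usable)
  p <- stats::wilcox.test(real[keep], shuf[keep], paired = TRUE,
                          exact = FALSE)$p.value
  # The two-sided signed-rank p alone can reject on order-free data:
  # each real ratio is a single draw of a right-skewed statistic whose
  # median sits below the shuffle mean. A sequence is claimed only when
  # the direction is positive (real ratios exceed the shuffle means).
  list(ratios = data.frame(unit_id = ids[keep], real = real[keep],
                           shuffled = shuf[keep],
                           stringsAsFactors = FALSE),
       p = p, median_diff = stats::median(real[keep] - shuf[keep]),
       n_units = length(keep), skipped = ids[!usable])
}

#' Peak-position histogram
#'
#' Fraction of units whose row peaks in each bin, plus the per-phase
#' aggregates between the event boundaries.
#'
#' @param mat a [build_sequence_matrix()] result.
#' @param include_flagged count flagged rows too (default FALSE).
#' @return list: `per_bin` (fractions, sum 1), `per_phase` (named
#'   fractions over the five phases), `n_units`.
#' @export
peak_histogram <- function(mat, include_flagged = FALSE) {
  stopifnot(inherits(mat, "sequence_matrix"))
  V <- mat$values
  keep <- if (include_flagged) rep(TRUE, nrow(V))
  else !(rownames(V) %in% mat$flagged)
  V <- V[keep, , drop = FALSE]
  B <- ncol(V)
  peaks <- apply(V, 1, which.max)
  per_bin <- tabulate(peaks, nbins = B) / nrow(V)
  cuts <- c(0, mat$boundaries, B)
  per_phase <- vapply(seq_len(5), function(i)
    sum(per_bin[(cuts[i] + 1L):cuts[i + 1L]]), numeric(1))
  names(per_phase) <- mat$phases
  list(per_bin = per_bin, per_phase = per_phase, n_units = nrow(V))
}
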