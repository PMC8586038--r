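# Spike-sorting quality gates applied before analysis: refractory-period
# (ISI) violation screen, isolation distance and L-ratio on waveform
# features, and duplicate-unit detection by spike-time coincidence.

#' Fraction of inter-spike intervals violating the refractory bound
#'
#' @param train a [spike_train] with at least 2 spikes.
#' @param threshold_s refractory bound in seconds (default 2 ms).
#' @return fraction in `[0, 1]`: `#(ISI < threshold) / #ISI`. Units are
#'   conventionally kept when this is below 0.01.
#' @export
isi_violation_fraction <- function(train, threshold_s = 0.002) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (length(t) < 2L)
    stop("isi_violation_fraction: need >= 2 spikes")
  isi <- diff(t)
  sum(isi < threshold_s) / length(isi)
}

#' Feature matrix for cluster-quality metrics
#'
#' Waveform features (rows = spikes, columns = features) with a cluster
#' label per spike; spikes not in the target cluster are the "noise" set.
#'
#' @param features numeric matrix, >= 2 columns.
#' @param labels vector of cluster ids, one per row.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, labels) {
  features <- as.matrix(features)
  if (ncol(features) < 2L)
    stop("feature_matrix: need >= 2 features")
  if (nrow(features) != length(labels))
    stop("feature_matrix: one label per spike required")
  structure(list(features = features, labels = labels),
            class = "feature_matrix")
}

# Squared Mahalanobis distance of every non-target spike to the target
# cluster's mean/covariance (n-1 divisor). Shared by both metrics.
target_mahalanobis <- function(fm, target) {
  stopifnot(inherits(fm, "feature_matrix"))
  in_target <- fm$labels == target
  X <- fm$features[in_target, , drop = FALSE]
  noise <- fm$features[!in_target, , drop = FALSE]
  n <- nrow(X)
  if (n < ncol(X) + 1L)
    stop("target cluster too small for covariance estimation (need >= ",
         ncol(X) + 1L, " spikes)")
  S <- stats::cov(X)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || !all(is.finite(S)) || det(S) <= 0)
    stop("degenerate target covariance (singular)")
  list(d2 = stats::mahalanobis(noise, colMeans(X), S), n = n,
       df = ncol(X))
}

#' Isolation distance of a sorted cluster
#'
#' The squared Mahalanobis distance (target-cluster mean and covariance)
#' of the n-th closest noise spike, where n is the target cluster size.
#' Values above 20 conventionally indicate a well-isolated unit.
#'
#' @param fm a [feature_matrix()].
#' @param target target cluster id.
#' @return non-negative scalar.
#' @export
isolation_distance <- function(fm, target) {
  m <- target_mahalanobis(fm, target)
  if (length(m$d2) < m$n)
    stop("isolation_distance: fewer noise spikes (", length(m$d2),
         ") than target-cluster spikes (", m$n, ")")
  sort(m$d2)[m$n]
}

#' L-ratio of a sorted cluster
#'
#' Sum over noise spikes of `1 - CDF_chisq(D^2, df = #features)` divided
#' by the target cluster size; values below 0.1 conventionally indicate a
#' clean unit.
#'
#' @inheritParams isolation_distance
#' @return non-negative scalar.
#' @export
l_ratio <- function(fm, target) {
  m <- target_mahalanobis(fm, target)
  sum(1 - stats::pchisq(m$d2, df = m$df)) / m$n
}

#' Spike-time coincidence between two units
#'
#' Fraction of spikes of the smaller train that have a spike of the other
#' train within `+/-coincidence_window_s`; pairs exceeding the duplicate
#' threshold are flagged so the lower-count unit can be dropped.
#'
#' @param train_a,train_b [spike_train]s (or bare time vectors), non-empty.
#' @param coincidence_window_s matching half-window, seconds (default 1 ms).
#' @param duplicate_threshold flag as duplicate above this fraction
#'   (default 0.5).
#' @return list: `coincidence_fraction`, `is_duplicate`.
#' @export
duplicate_pair <- function(train_a, train_b, coincidence_window_s = 0.001,
                           duplicate_threshold = 0.5) {
  ta <- if (inherits(train_a, "spike_train")) train_a$times else
    as.numeric(train_a)
  tb <- if (inherits(train_b, "spike_train")) train_b$times else
    as.numeric(train_b)
  if (!length(ta) || !length(tb))
    stop("duplicate_pair: empty spike train")
  if (length(ta) > length(tb)) { tmp <- ta; ta <- tb; tb <- tmp }
  # for each spike of the smaller train, nearest spike of the larger one
  idx <- findInterval(ta, tb)
  d_lo <- ifelse(idx >= 1L, ta - tb[pmax(idx, 1L)], Inf)
  d_hi <- ifelse(idx < length(tb), tb[pmin(idx + 1L, length(tb))] - ta, Inf)
  frac <- mean(pmin(d_lo, d_hi) <= coincidence_window_s)
  list(coincidence_fraction = frac,
       is_duplicate = frac > duplicate_threshold)
}

#' Quality-control report for a session
#'
#' Applies the three gates (ISI violations < 1%, isolation distance > 20,
#' L-ratio < 0.1 where features are available) and the duplicate screen,
#' and reports which units survive.
#'
#' @param s a [session].
#' @param features optional named list of [feature_matrix()] per unit (one
#'   matrix with the unit's spikes labeled vs noise); when absent the
#'   Mahalanobis gates are reported as `NA` and not enforced.
#' @param isi_max,iso_min,lratio_max gate thresholds.
#' @return data.frame: `unit_id`, `n_spikes`, `isi_violation_fraction`,
#'   `isolation_distance`, `l_ratio`, `duplicate_of`, `kept`.
#' @export
qc_report <- function(s, features = NULL, isi_max = 0.01, iso_min = 20,
                      lratio_max = 0.1) {
  trains <- s$spike_trains
  ids <- vapply(trains, function(st) st$unit_id, character(1))
  n <- vapply(trains, function(st) length(st$times), integer(1))
  isi <- vapply(trains, function(st)
    if (length(st$times) >= 2L) isi_violation_fraction(st) else NA_real_,
    numeric(1))
  iso <- lr <- rep(NA_real_, length(trains))
  for (i in seq_along(trains)) {
    fm <- features[[ids[i]]]
    if (!is.null(fm)) {
      iso[i] <- isolation_distance(fm, target = ids[i])
      lr[i] <- l_ratio(fm, target = ids[i])
    }
  }
  dup_of <- rep(NA_character_, length(trains))
  ord <- order(n, decreasing = TRUE)   # keep the higher-count unit
  for (a in seq_along(ord)) for (b in seq_len(a - 1L)) {
    i <- ord[a]; j <- ord[b]
    if (!is.na(dup_of[j]) || n[i] == 0L || n[j] == 0L) next
    if (duplicate_pair(trains[[i]], trains[[j]])$is_duplicate)
      dup_of[i] <- ids[j]
  }
  kept <- (is.na(isi) | isi < isi_max) &
    (is.na(iso) | iso > iso_min) &
    (is.na(lr) | lr < lratio_max) &
    is.na(dup_of)
  data.frame(unit_id = ids, n_spikes = n, isi_violation_fraction = isi,
             isolation_distance = iso, l_ratio = lr,
             duplicate_of = dup_of, kept = kept,
             stringsAsFactors = FALSE)
}
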