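# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average with edge truncation
#'
#' Boxcar-smooths a numeric vector; at the edges the window is truncated to
#' the available samples so no values are lost and no padding is invented.
#'
#' @param x numeric vector.
#' @param width window width in samples (odd widths are symmetric; even
#'   widths take one more sample on the left).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
moving_average <- function(x, width) {
  stopifnot(width >= 1)
  if (width == 1L) return(x)
  n <- length(x)
  half_lo <- ceiling((width - 1) / 2)
  half_hi <- floor((width - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Count spikes of a sorted vector falling in [start, end) for vectors of
# interval bounds. Half-open so abutting phases never double-count:
# #(t < end) - #(t < start).
count_in_intervals <- function(times, starts, ends) {
  findInterval(ends, times, left.open = TRUE) -
    findInterval(starts, times, left.open = TRUE)
}

# Total spikes in a list/matrix of [start, end) intervals (2-column matrix).
count_spikes <- function(times, intervals) {
  if (length(times) == 0L || nrow(intervals) == 0L) return(0L)
  sum(count_in_intervals(times, intervals[, 1L], intervals[, 2L]))
}

as_interval_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x[, 1:2]))
  if (is.list(x)) return(do.call(rbind, lapply(x, function(i) i[1:2])))
  matrix(x, ncol = 2, byrow = TRUE)
}

# Minimal unique-assignment solver: maximize total score assigning each row
# (cluster) to a distinct column (template). Exhaustive for <= 8 rows,
# greedy otherwise; k here never exceeds the archetype count.
assign_unique <- function(score) {
  k <- nrow(score); m <- ncol(score)
  stopifnot(k <= m)
  if (k <= 8L) {
    cols <- seq_len(m)
    best <- NULL; best_val <- -Inf
    rec <- function(row, used, pick, val) {
      if (row > k) {
        if (val > best_val) { best_val <<- val; best <<- pick }
        return(invisible())
      }
      for (j in setdiff(cols, used)) {
        v <- val + score[row, j]
        if (v + (k - row) * max(score) < best_val) next
        rec(row + 1L, c(used, j), c(pick, j), v)
      }
    }
    rec(1L, integer(0), integer(0), 0)
    best
  } else {
    pick <- integer(k); used <- logical(m)
    for (i in order(apply(score, 1, max), decreasing = TRUE)) {
      j <- which.max(replace(score[i, ], used, -Inf))
      pick[i] <- j; used[j] <- TRUE
    }
    pick
  }
}
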