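# Hunting-efficiency metrics derived from an ethogram: the seven
# parameters quantifying how efficiently a trial progressed from prey
# introduction to capture and eating.

#' Compute hunting metrics from an ethogram
#'
#' Per trial: latency to attack (`first_attack - cricket_in`), chase
#' rounds (chase intervals before the first attack), attack efficiency
#' (`1 / attack attempts before capture`), attack segments (attack
#' intervals before capture), capture duration
#' (`capture - first_attack`, successful trials only) and eating
#' duration; per session: the capture success rate in percent. Failed
#' trials (no `capture` event, e.g. timed out) keep their place in the
#' success-rate denominator and report missing capture-dependent values.
#'
#' @param eth an [ethogram] whose every trial has a `cricket_in` event.
#' @return object of class `hunting_metrics`: `trials` (data.frame with
#'   one row per trial: `trial_id`, `latency_to_attack_s`,
#'   `chase_rounds`, `attack_efficiency`, `attack_segments`,
#'   `capture_duration_s`, `eating_duration_s`, `captured`) and
#'   `capture_success_rate` (percent).
#' @export
compute_metrics <- function(eth) {
  stopifnot(inherits(eth, "ethogram"))
  ev <- eth$events
  iv <- eth$intervals
  trials <- sort(unique(ev$trial_id[ev$name == "cricket_in"]))
  if (!length(trials))
    stop("compute_metrics: no trial with a cricket_in event")

  one <- function(tr) {
    e <- ev[ev$trial_id == tr, , drop = FALSE]
    i <- iv[iv$trial_id == tr, , drop = FALSE]
    at <- function(nm) { t <- e$time_s[e$name == nm]
      if (length(t)) min(t) else NA_real_ }
    ci <- at("cricket_in"); fa <- at("first_attack"); cap <- at("capture")
    if (!is.na(cap) && !is.na(fa) && cap < fa)
      stop("compute_metrics: capture before first_attack in trial ", tr)
    chases <- i[i$label == "chase", , drop = FALSE]
    attacks <- i[i$label == "attack", , drop = FALSE]
    eat <- i[i$label == "eating", , drop = FALSE]
    attempts <- e$time_s[e$name == "attack_attempt"]
    chase_rounds <- if (is.na(fa)) nrow(chases)
    else sum(chases$start_s < fa)
    n_att <- if (is.na(cap)) length(attempts)
    else sum(attempts <= cap)
    data.frame(
      trial_id = tr,
      latency_to_attack_s = fa - ci,
      chase_rounds = chase_rounds,
      attack_efficiency = if (!is.na(cap) && n_att > 0) 1 / n_att
      else NA_real_,
      attack_segments = if (is.na(cap)) nrow(attacks)
      else sum(attacks$start_s < cap),
      capture_duration_s = if (!is.na(cap)) cap - fa else NA_real_,
      eating_duration_s = if (nrow(eat)) sum(eat$end_s - eat$start_s)
      else NA_real_,
      captured = !is.na(cap))
  }
  tab <- do.call(rbind, lapply(trials, one))
  structure(list(trials = tab,
                 capture_success_rate = 100 * mean(tab$captured)),
            class = "hunting_metrics")
}

#' @export
print.hunting_metrics <- function(x, ...) {
  cat(sprintf("<hunting_metrics> %d trial(s), capture success %.1f%%\n",
              nrow(x$trials), x$capture_success_rate))
  print(x$trials)
  invisible(x)
}

#' Aggregate hunting metrics across sessions
#'
#' Mean and SEM per metric per group; missing values are excluded with
#' their counts reported. A single observation reports `NA` SEM.
#'
#' @param metrics list of [compute_metrics()] results (one per session).
#' @param groups group label per session (recycled if length 1).
#' @return data.frame: `group`, `metric`, `mean`, `sem`, `n`,
#'   `n_missing`.
#' @export
aggregate_metrics <- function(metrics, groups = "all") {
  stopifnot(length(metrics) >= 1)
  groups <- rep_len(as.character(groups), length(metrics))
  cols <- c("latency_to_attack_s", "chase_rounds", "attack_efficiency",
            "attack_segments", "capture_duration_s", "eating_duration_s")
  long <- do.call(rbind, lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    stopifnot(inherits(m, "hunting_metrics"))
    tr <- m$trials
    rbind(
      do.call(rbind, lapply(cols, function(cl)
        data.frame(group = groups[i], metric = cl, value = tr[[cl]]))),
      data.frame(group = groups[i], metric = "capture_success_rate",
                 value = m$capture_success_rate))
  }))
  out <- do.call(rbind, lapply(split(long, long[c("group", "metric")],
                                     drop = TRUE), function(d) {
    v <- d$value[!is.na(d$value)]
    if (!length(v)) stop("aggregate_metrics: empty group for metric ",
                         d$metric[1])
    data.frame(group = d$group[1], metric = d$metric[1],
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               n = length(v), n_missing = sum(is.na(d$value)))
  }))
  rownames(out) <- NULL
  out
}
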