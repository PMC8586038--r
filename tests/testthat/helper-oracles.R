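# Brute-force oracles, deliberately independent of the implementation
# paths they check.

# Squared Mahalanobis distances via an explicit covariance inverse.
oracle_mahal <- function(X, noise) {
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / (nrow(X) - 1)
  Sinv <- solve(S)
  apply(noise, 1, function(x) drop(t(x - mu) %*% Sinv %*% (x - mu)))
}

# Exhaustive complete-linkage agglomeration (max inter-group distance).
oracle_complete_linkage <- function(X) {
  groups <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  merges <- list()
  while (length(groups) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      d <- max(D[groups[[i]], groups[[j]]])
      if (d < best_d) { best_d <- d; best <- c(j, i) }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(groups[[best[1]]], groups[[best[2]]])),
           height = best_d)
    groups[[best[2]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[1]]] <- NULL
  }
  merges
}

# Loop-and-average spike-triggered EMG with explicit smoothing,
# downsampling and boxcar baseline correction.
oracle_stemg <- function(spikes, emg, half_n = 400, step = 5,
                         boxcar = 21) {
  sr <- emg$sample_rate
  snips <- list()
  for (t in spikes) {
    c0 <- round((t - emg$t0) * sr) + 1
    if (c0 - half_n < 1 || c0 + half_n > length(emg$signal)) next
    snips[[length(snips) + 1]] <- emg$signal[(c0 - half_n):(c0 + half_n)]
  }
  m <- Reduce(`+`, snips) / length(snips)
  ma <- function(x, w) {
    n <- length(x); out <- numeric(n)
    hl <- ceiling((w - 1) / 2); hh <- floor((w - 1) / 2)
    for (i in seq_len(n)) {
      lo <- max(1, i - hl); hi <- min(n, i + hh)
      out[i] <- mean(x[lo:hi])
    }
    out
  }
  sm <- ma(m, step)[seq(1, 2 * half_n + 1, by = step)]
  sm - ma(sm, boxcar)
}

# Deterministic five-trial hunting ethogram with known answers: trial 1
# has a 12.4-s latency to attack and 5 attack attempts; trials 1-3 end
# in capture (60% success), trials 4-5 time out.
hand_ethogram <- function() {
  iv <- list(); ev <- list()
  t0 <- 60
  for (tr in 1:5) {
    captured <- tr <= 3
    lat <- if (tr == 1) 12.4 else 8
    iv[[tr]] <- data.frame(
      trial_id = tr,
      label = c("introduction", "chase", "chase", "attack",
                if (captured) "eating"),
      start_s = t0 + c(0, 2, lat - 3, lat, if (captured) lat + 20),
      end_s = t0 + c(2, lat - 3, lat, lat + 20, if (captured) lat + 50))
    ev_names <- c("cricket_in", "chase_onset", "first_attack",
                  rep("attack_attempt", 5),
                  if (captured) c("capture", "eating_onset"),
                  "trial_end")
    ev_times <- t0 + c(0, 2, lat, lat + (1:5) * 2,
                       if (captured) c(lat + 20, lat + 20),
                       if (captured) lat + 50 else 360)
    ev[[tr]] <- data.frame(trial_id = tr, name = ev_names,
                           time_s = ev_times)
    t0 <- t0 + 400
  }
  iv[[6]] <- data.frame(trial_id = 0L, label = "baseline", start_s = 0,
                        end_s = 60)
  ethogram(do.call(rbind, iv), do.call(rbind, ev))
}
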