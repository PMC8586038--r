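# minimal hand-built null for arithmetic checks
list_to_null <- function(mean, sd)
  structure(list(resampled_rates = numeric(0), baseline_mean = mean,
                 baseline_sd = sd, bin_rates = numeric(0)),
            class = "baseline_null")

test_that("phase_mean_rate equals the concatenate-and-count oracle", {
  # 10 spikes, 6 of them inside the 2 s of intervals -> 3 spikes/s
  expect_equal(phase_mean_rate(c(0.1, 0.5, 1.1, 1.5, 1.9, 2.5, 3.1, 3.3,
                                 3.5, 3.9),
                               rbind(c(0, 1), c(3, 4))),
               3.0)
  # 10 spikes in 2 s -> 5 spikes/s
  expect_equal(phase_mean_rate(seq(0.1, 1.9, by = 0.2), rbind(c(0, 2))),
               5.0)
  expect_equal(phase_mean_rate(numeric(0), rbind(c(0, 2))), 0)
  set.seed(1)
  t <- sort(runif(500, 0, 100))
  iv <- rbind(c(5, 20), c(30, 31.5), c(70, 90))
  want <- sum(vapply(seq_len(nrow(iv)), function(i)
    sum(t >= iv[i, 1] & t < iv[i, 2]), numeric(1))) /
    sum(iv[, 2] - iv[, 1])
  expect_equal(phase_mean_rate(t, iv), want, tolerance = 1e-12)
  expect_error(phase_mean_rate(t, rbind(c(5, 5))), "> 0")
})

test_that("baseline_null degenerate cases behave as documented", {
  # perfectly regular train: every 1-s bin holds the same count, so all
  # resampled rates equal the true rate
  t <- seq(0.05, 59.95, by = 0.2)  # 5 spikes/s, 5 per bin
  set.seed(2)
  bn <- baseline_null(t, c(0, 60), phase_duration_s = 10,
                      n_resamples = 200)
  expect_true(all(abs(bn$resampled_rates - 5) < 1e-12))
  expect_equal(bn$baseline_mean, 5)
  expect_equal(bn$baseline_sd, 0)
  # empty baseline train
  bn0 <- baseline_null(numeric(0), c(0, 60), 10, 200)
  expect_true(all(bn0$resampled_rates == 0))
  expect_error(baseline_null(t, c(10, 10), 5, 200), "empty baseline")
})

test_that("resampled mean tracks the true rate on Poisson baselines", {
  set.seed(3)
  devs <- replicate(20, {
    t <- sort(runif(rpois(1, 600), 0, 60))  # ~10 spikes/s
    bn <- baseline_null(t, c(0, 60), 8, 500)
    mean(bn$resampled_rates) - length(t) / 60
  })
  expect_lt(max(abs(devs)), 0.6)
})

test_that("classification edges and the z-score hand check are exact", {
  set.seed(4)
  t <- sort(runif(300, 0, 60))
  bn <- baseline_null(t, c(0, 60), 10, 300)
  expect_equal(classify_response(max(bn$resampled_rates) + 1, bn),
               "excited")
  expect_equal(classify_response(-0.01, bn), "inhibited")
  # hand-checkable z: baseline 1-s bins {4, 5, 6} -> mean 5, sd 1;
  # phase rate 7 gives z = 2 exactly
  t3 <- c(sort(runif(4, 0, 1)), sort(runif(5, 1, 2)), sort(runif(6, 2, 3)))
  bn3 <- baseline_null(t3, c(0, 3), 1, 100)
  expect_equal(bn3$baseline_mean, 5)
  expect_equal(bn3$baseline_sd, 1)
  expect_equal(zscore_phase(7, bn3), 2.0)
  # z invariances: shift both by c and scale by k
  expect_equal(zscore_phase(7 + 5, list_to_null(10, 1)), 2)
  expect_equal(zscore_phase(14, list_to_null(10, 2)), 2)
  # degenerate baseline errors
  bn_const <- list_to_null(5, 0)
  expect_error(zscore_phase(7, bn_const), "degenerate")
})

test_that("phase_responses builds the full z-table and excludes degenerates", {
  pop <- small_population(seed = 5, n_per_type = 2)
  set.seed(6)
  pr <- phase_responses(pop$session, n_resamples = 200)
  expect_equal(ncol(pr$zscores), 5)
  expect_true(all(pr$zscores[, "baseline"] == 0))
  expect_true(all(is.finite(pr$zscores)))
  expect_setequal(unique(pr$responses$phase),
                  c("introduction", "chase", "attack", "eating"))
  expect_true(all(pr$responses$label %in%
                    c("excited", "inhibited", "nonresponsive")))
  # planted excitation is recovered: type I units excited in chase
  gt <- pop$ground_truth
  i_units <- gt$unit_id[gt$archetype == "I"]
  lab <- pr$responses[pr$responses$phase == "chase" &
                        pr$responses$unit_id %in% i_units, "label"]
  expect_true(all(lab == "excited"))
})

test_that("velocity tuning is exact on proportional input and errors on constants", {
  # rate exactly proportional to speed: one spike block per bin
  sr <- 10; dur <- 100; bin_s <- 0.5
  speed <- rep_len(rep(c(2, 4, 8, 16), each = sr * bin_s), sr * dur)
  vt <- velocity_trace(speed, sr)
  set.seed(7)
  nb <- dur / bin_s
  t <- unlist(lapply(seq_len(nb), function(b) {
    v <- speed[(b - 1) * sr * bin_s + 1]
    sort(runif(v, (b - 1) * bin_s, b * bin_s - 1e-6))
  }))
  r <- velocity_tuning(spike_train("u", sort(t), span = c(0, dur)), vt,
                       bin_s = bin_s)
  expect_equal(r$r, 1, tolerance = 1e-9)
  expect_error(velocity_tuning(spike_train("u", sort(t),
                                           span = c(0, dur)),
                               velocity_trace(rep(3, 1000), sr)),
               "constant")
})

test_that("stimulus responsiveness detects planted bursts only", {
  set.seed(8)
  base <- sort(runif(600, 0, 60))  # ~10 Hz
  # a strong burst in one 100-ms bin of the stimulus window
  burst <- sort(runif(30, 62.45, 62.55))
  expect_true(stimulus_responsive(sort(c(base, burst)), c(62, 64),
                                  c(0, 60)))
  # homogeneous unit with modest fluctuation stays below 2.5 sd
  expect_false(stimulus_responsive(base[base < 50], c(50, 50.4), c(0, 40),
                                   z_threshold = 10))
  # one spike per 1-s baseline bin: constant counts, sd = 0
  expect_error(stimulus_responsive(c(0.5, 1.5, 2.5, 3.5), c(10, 11),
                                   c(0, 4), bin_s = 1), "degenerate")
})

test_that("assessment cells require onset-locked firing", {
  span <- c(0, 300)
  onsets <- seq(20, 280, by = 30)
  # unit firing only inside assessment windows
  set.seed(9)
  t <- sort(unlist(lapply(onsets, function(o) runif(20, o, o + 2))))
  expect_true(assessment_cell(spike_train("a", t, span = span), onsets))
  # silent unit: identical samples, never significant
  expect_false(assessment_cell(spike_train("s", numeric(0), span = span),
                               onsets))
})
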