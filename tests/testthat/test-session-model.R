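test_that("constructors enforce the declared invariants", {
  expect_error(spike_train("u1", c(0.2, 0.1), span = c(0, 1)),
               "strictly increasing")
  expect_error(spike_train("u1", c(-0.5, 0.1), span = c(0, 1)),
               "negative")
  expect_error(spike_train("u1", c(0.1, 2), span = c(0, 1)),
               "outside span")
  expect_error(ethogram(data.frame(trial_id = 1L, label = "chase",
                                   start_s = 5, end_s = 5)),
               "start >= end")
  expect_error(ethogram(data.frame(trial_id = c(1L, 1L),
                                   label = c("chase", "attack"),
                                   start_s = c(0, 3), end_s = c(5, 8))),
               "overlapping")
  # overlap across different trials is fine
  expect_s3_class(ethogram(data.frame(trial_id = c(1L, 2L),
                                      label = c("chase", "attack"),
                                      start_s = c(0, 3),
                                      end_s = c(5, 8))), "ethogram")
  expect_error(ethogram(data.frame(trial_id = 1L, label = "chase",
                                   start_s = 0, end_s = 5),
                        data.frame(trial_id = 1L,
                                   name = c("cricket_in", "first_attack"),
                                   time_s = c(10, 2))),
               "canonical order")
  expect_error(velocity_trace(c(1, -2), 10), ">= 0")
  expect_error(laser_train(c(0.2, 0.1)), "strictly increasing")
})

test_that("phase_intervals returns ordered intervals and rejects unknown labels", {
  eth <- toy_ethogram(n_trials = 2)
  ch <- phase_intervals(eth, "chase")
  expect_equal(nrow(ch), 2)
  expect_true(all(diff(ch[, "start_s"]) > 0))
  expect_equal(sum(ch[, 2] - ch[, 1]), 10)   # two 5-s chases
  # absent canonical label -> empty, not an error
  eth2 <- ethogram(data.frame(trial_id = 1L, label = "chase",
                              start_s = 0, end_s = 5))
  expect_equal(nrow(phase_intervals(eth2, "eating")), 0)
  expect_error(phase_intervals(eth2, "grooming"), "unknown")
  # custom labels present in the ethogram are retrievable
  eth3 <- ethogram(data.frame(trial_id = 1L, label = "custom_phase",
                              start_s = 1, end_s = 2))
  expect_equal(nrow(phase_intervals(eth3, "custom_phase")), 1)
})

test_that("minimal manifest round-trip reproduces the session", {
  eth <- ethogram(data.frame(trial_id = 0L, label = "baseline",
                             start_s = 0, end_s = 60))
  s <- session(list(spike_train("u1", c(0.1, 0.2), span = c(0, 60))), eth)
  d <- withr::local_tempdir()
  man <- write_session(s, d)
  s2 <- load_session(man)
  expect_length(s2$spike_trains, 1)
  expect_equal(s2$spike_trains[[1]]$times, c(0.1, 0.2), tolerance = 1e-9)
})

test_that("round-trip is the identity on random sessions to 1e-9 s", {
  pop <- small_population(seed = 7, n_per_type = 2)
  s <- pop$session
  d <- withr::local_tempdir()
  s2 <- load_session(write_session(s, d))
  expect_equal(length(s2$spike_trains), length(s$spike_trains))
  for (i in seq_along(s$spike_trains)) {
    expect_equal(s2$spike_trains[[i]]$unit_id, s$spike_trains[[i]]$unit_id)
    expect_lt(max(abs(s2$spike_trains[[i]]$times -
                        s$spike_trains[[i]]$times), 0), 1e-9)
    expect_equal(s2$spike_trains[[i]]$waveform,
                 s$spike_trains[[i]]$waveform, tolerance = 1e-9)
  }
  expect_equal(s2$ethogram$intervals$start_s, s$ethogram$intervals$start_s,
               tolerance = 1e-9)
  expect_equal(s2$ethogram$events$name, s$ethogram$events$name)
  expect_equal(s2$laser$pulse_onsets, s$laser$pulse_onsets,
               tolerance = 1e-9)
  expect_equal(s2$emg$signal, s$emg$signal, tolerance = 1e-9)
  expect_equal(s2$velocity$speed, s$velocity$speed, tolerance = 1e-9)
})

test_that("write -> load -> write is byte-identical (idempotence)", {
  pop <- small_population(seed = 3, n_per_type = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(pop$session, d1)
  write_session(load_session(d1), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)), label = f)
  }
})

test_that("optional components are omitted from the manifest", {
  eth <- toy_ethogram(1)
  s <- session(list(spike_train("u1", 1, span = c(0, 120))), eth)
  d <- withr::local_tempdir()
  man <- jsonlite::read_json(write_session(s, d))
  expect_null(man$components$velocity)
  expect_null(man$components$emg)
  expect_null(man$components$laser)
  expect_false(file.exists(file.path(d, "velocity.csv")))
})

test_that("loading a corrupted bundle names the offending unit", {
  eth <- ethogram(data.frame(trial_id = 0L, label = "baseline",
                             start_s = 0, end_s = 60))
  s <- session(list(spike_train("u7", c(0.1, 0.2), span = c(0, 60))), eth)
  d <- withr::local_tempdir()
  man <- write_session(s, d)
  sp <- utils::read.csv(file.path(d, "spikes.csv"))
  sp$time_s <- rev(sp$time_s)
  utils::write.csv(sp, file.path(d, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(load_session(man), "u7")
  expect_error(load_session(file.path(d, "nope.json")), "not found")
})

test_that("sessions reject duplicate unit ids and mixed waveform lengths", {
  eth <- toy_ethogram(1)
  t1 <- spike_train("u1", 1, span = c(0, 120))
  expect_error(session(list(t1, t1), eth), "duplicated unit ids")
  t2 <- spike_train("u2", 1, span = c(0, 120), waveform = 1:8)
  t3 <- spike_train("u3", 1, span = c(0, 120), waveform = 1:9)
  expect_error(session(list(t2, t3), eth), "share one length")
})
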