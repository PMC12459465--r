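# Event detection, frequency estimation, release-time histograms,
# kinetics, and the stimulation protocol schedules.

test_that("event trains validate their windows", {
  tr <- event_train(c(5, 1, 3), c(0, 10))
  expect_equal(tr$event_times, c(1, 3, 5))
  expect_error(event_train(c(12), c(0, 10)), "inside the recording")
  expect_error(event_train(numeric(0), c(10, 0)), "start < end")
  expect_error(event_train(1, c(0, 10), stim_window = c(5, 12)),
               "inside the recording")
})

test_that("detector finds injected transients and ignores flat traces", {
  n <- 1200; dt <- 0.05
  flat <- roi_trace((0:(n - 1)) * dt, rep(2, n))
  expect_length(detect_events(flat)$event_times, 0L)
  set.seed(61)
  v <- rnorm(n, 10, 0.2)
  onset <- 400
  v[onset:(onset + 20)] <- v[onset:(onset + 20)] + 2 * exp(-(0:20) / 8)  # 10 SD
  one <- detect_events(roi_trace((0:(n - 1)) * dt, v))
  expect_length(one$event_times, 1L)
  expect_equal(one$event_times, (onset - 1) * dt, tolerance = 2 * dt)
})

test_that("detector recall and precision on a 20-event synthetic train", {
  set.seed(62)
  dt <- 0.05; n <- 4000
  tt <- (0:(n - 1)) * dt
  true_times <- sort(sample(seq(5, 190, by = 5), 20))   # well separated
  v <- rnorm(n, 10, 0.15)
  for (t0 in true_times) {
    i <- which(tt >= t0)[1]
    k <- i:min(i + 30, n)
    v[k] <- v[k] + 1.5 * exp(-(seq_along(k) - 1) * dt / 0.5)
  }
  det <- detect_events(roi_trace(tt, v))$event_times
  matched <- sum(vapply(true_times,
                        function(t0) any(abs(det - t0) < 0.5), logical(1)))
  recall <- matched / length(true_times)
  precision <- sum(vapply(det, function(d)
    any(abs(true_times - d) < 0.5), logical(1))) / length(det)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("event frequency is count over window length", {
  tr <- event_train(seq(0.5, 59.5, length.out = 30), c(0, 60))
  expect_equal(event_frequency(tr, c(0, 60)), 0.5)
  expect_equal(event_frequency(event_train(numeric(0), c(0, 60)), c(0, 60)), 0)
  expect_error(event_frequency(tr, c(10, 10)), "positive length")
  # invariant to shifting train and window together
  sh <- event_train(tr$event_times + 100, c(100, 160))
  expect_equal(event_frequency(sh, c(100, 160)),
               event_frequency(tr, c(0, 60)))
})

test_that("frequency estimator is unbiased on homogeneous Poisson trains", {
  lambda <- 0.3
  est <- vapply(1:100, function(s) {
    ev <- simulate_event_train(lambda, lambda, seed = 6200 + s)
    event_frequency(ev$train, c(0, 180))
  }, numeric(1))
  se <- sqrt(lambda / 180) / sqrt(100)
  expect_lt(abs(mean(est) - lambda), 3 * se)
})

test_that("release-time histogram bins, conserves and rejects bad widths", {
  trains <- list(event_train(c(0, 5, 9.99, 10, 55, 59.999), c(0, 60)),
                 event_train(c(25, 60), c(0, 70)))
  h <- release_time_histogram(trains, bin_width = 10, window = c(0, 60))
  expect_length(h, 6L)
  expect_equal(sum(h), 7L)          # the event at exactly 60 s is excluded
  expect_equal(unname(h[1]), 3L)    # [0,10): 0, 5, 9.99
  expect_equal(unname(h[3]), 1L)    # [20,30): 25
  expect_error(release_time_histogram(trains, bin_width = 7), "divide")
  # counts conserved under any divisor bin width
  for (bw in c(5, 6, 20)) {
    expect_equal(sum(release_time_histogram(trains, bw, c(0, 60))), 7L)
  }
})

test_that("uniform event times give an approximately flat histogram", {
  reject <- 0L
  for (s in 1:20) {
    set.seed(6300 + s)
    tr <- event_train(runif(120, 0, 60), c(0, 60))
    h <- release_time_histogram(tr, 10, c(0, 60))
    p <- suppressWarnings(chisq.test(as.integer(h))$p.value)
    if (p < 0.01) reject <- reject + 1L
  }
  expect_lte(reject, 3L)   # ~1% nominal rate over 20 draws
})

test_that("event kinetics recover ramp rise time and exponential decay", {
  dt <- 0.01
  tt <- seq(0, 6, by = dt)
  ramp <- approx(c(0, 1, 1.1, 6), c(0, 0, 1, 1), xout = tt)$y  # 100-ms ramp
  v <- ifelse(tt <= 1.1, ramp, exp(-(tt - 1.1) / 0.5))
  k <- event_kinetics(tt, v)
  expect_equal(k$rise_time, 0.08, tolerance = 0.015)  # 10-90% of a linear ramp
  expect_false(k$decay_flagged)
  expect_equal(k$decay_time, 0.5, tolerance = 0.05)
  flat <- c(rep(0, 10), seq(0, 1, length.out = 11), rep(1, 30))
  kf <- event_kinetics(seq_along(flat) * dt, flat)
  expect_true(kf$decay_flagged)
  expect_true(is.na(kf$decay_time))
})

test_that("stimulation schedules match the LTP protocol arithmetic", {
  el <- stimulus_protocol("electrical")
  expect_length(el$pulse_onsets, 600L)             # 30 bursts x 20 pulses
  expect_equal(unique(diff(el$burst_onsets)), 2)   # 0.5 Hz
  expect_equal(el$duration, 60)
  expect_equal(el$pulse_width, 1e-3)
  un <- stimulus_protocol("uncaging")
  expect_length(un$pulse_onsets, 30L)
  expect_equal(un$pulse_width, 6e-3)
})
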