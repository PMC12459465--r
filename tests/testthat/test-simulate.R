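# The synthetic-data generator: determinism, photon conservation, and
# round-trip recovery through the analysis modules.

test_that("photon simulation conserves counts and is seed-deterministic", {
  par <- decay_params(p_ad = 0.3, tau_ad = 1.3, tau_g = 0.2, t0 = 1)
  h1 <- simulate_photon_histogram(par, 12345, seed = 71)
  expect_equal(sum(h1$counts), 12345)
  h2 <- simulate_photon_histogram(par, 12345, seed = 71)
  expect_identical(h1$counts, h2$counts)
  h3 <- simulate_photon_histogram(par, 12345, seed = 72)
  expect_false(identical(h1$counts, h3$counts))
})

test_that("simulated arrivals match the closed-form mixture mean", {
  # pure donor, t0 = 0: sample mean ~ tau_d
  h0 <- simulate_photon_histogram(
    decay_params(p_ad = 0, tau_ad = 1.3, tau_g = 1e-6, t0 = 0),
    3e5, period = 40, seed = 73)
  expect_equal(mean_arrival_time(h0), 2.6, tolerance = 0.02)
  # generic params: <t> ~ t0 + (p_d tau_d^2 + p_ad tau_ad^2)/(p_d tau_d + p_ad tau_ad)
  h <- simulate_photon_histogram(
    decay_params(p_ad = 0.3, tau_ad = 1.3, tau_g = 0.2, t0 = 1),
    3e5, period = 40, seed = 74)
  expect_equal(mean_arrival_time(h), 1 + 2.370588, tolerance = 0.02)
})

test_that("FLIM series puts free donor in the background", {
  sim <- simulate_flim_series(rep(0.4, 2), dim = c(8L, 8L),
                              photons_per_frame = 2e4,
                              background_photons = 800, seed = 75)
  lm <- lifetime_map(sim$stack$frames[[1]], sim$stack$bin_edges, t0 = 1,
                     min_photons = 100)
  bg <- lm$mask
  bg[sim$roi] <- FALSE
  expect_equal(mean(lm$mean_tau[bg], na.rm = TRUE), 2.6, tolerance = 0.05)
})

test_that("spine movies carry 30 pulses and honour reporter mode", {
  sc <- spine_scenario("SEP")
  mv <- simulate_spine_movie(sc, n_spines = 2L, seed = 76)
  expect_length(mv$ground_truth$pulse_times, 30L)
  expect_equal(diff(mv$ground_truth$pulse_times)[1], 2.048)
  # zero release amplitude: reporter tracks volume up to noise
  sc0 <- spine_scenario("SEP", release_amplitude = 0, noise_sd = 0.01)
  mv0 <- simulate_spine_movie(sc0, n_spines = 1L, seed = 77)
  d <- mv0$spines[[1]]$reporter$f - mv0$spines[[1]]$volume$f
  expect_lt(abs(mean(d)), 1)           # a.u. at baseline 100
  # Gamillus mode adds no release transients regardless of amplitude
  mvg <- simulate_spine_movie(spine_scenario("Gamillus", noise_sd = 0),
                              n_spines = 1L, seed = 78)
  dg <- mvg$spines[[1]]$reporter$f - mvg$spines[[1]]$volume$f
  expect_equal(max(abs(dg)), 0)
})

test_that("sweep pipeline recovers the mean release amplitude from ground truth", {
  # volume transient off and a release decay short enough that one pulse's
  # transient has died away before the next sweep's baseline frames, so the
  # per-sweep normalization sees each release in isolation
  sc <- spine_scenario("SEP", release_prob = 1, release_decay = 0.4,
                       volume_peak = 0, volume_sustained = 0,
                       noise_sd = 0.005)
  mv <- simulate_spine_movie(sc, n_spines = 6L, seed = 79)
  diffs <- vapply(mv$spines, function(sp) {
    pk_r <- peak_response(average_sweeps(normalize_sweeps(
      segment_sweeps(sp$reporter)), 2:18))
    pk_v <- peak_response(average_sweeps(normalize_sweeps(
      segment_sweeps(sp$volume)), 2:18))
    pk_r - pk_v
  }, numeric(1))
  # expected peak: amplitude attenuated by the exponential decay over the
  # three post-pulse frames; the pulse falls midway between frames 2 and 3,
  # so frames 3-5 sample the transient at lags of 0.5, 1.5, 2.5 intervals
  lag <- (c(1, 2, 3) - 0.5) * sc$frame_interval
  expected <- sc$release_amplitude * mean(exp(-lag / sc$release_decay))
  expect_lt(abs(mean(diffs) - expected), 0.15 * expected)
})

test_that("event trains follow the basal/stimulated rate structure", {
  ev <- simulate_event_train(0, 0.5, seed = 80)
  expect_true(all(ev$train$event_times >= 64 & ev$train$event_times <= 124))
  est_b <- vapply(1:100, function(s)
    event_frequency(simulate_event_train(0.1, 0.6, seed = 800 + s)$train,
                    c(0, 60)), numeric(1))
  est_s <- vapply(1:100, function(s)
    event_frequency(simulate_event_train(0.1, 0.6, seed = 800 + s)$train,
                    c(64, 124)), numeric(1))
  expect_lt(abs(mean(est_b) - 0.1), 3 * sqrt(0.1 / 60) / 10)
  expect_lt(abs(mean(est_s) - 0.6), 3 * sqrt(0.6 / 60) / 10)
})

test_that("identical seeds give identical datasets end to end", {
  a <- simulate_spine_movie(spine_scenario("SEP"), 3L, seed = 81)
  b <- simulate_spine_movie(spine_scenario("SEP"), 3L, seed = 81)
  expect_identical(a, b)
  e1 <- simulate_event_train(0.2, 0.5, seed = 82)
  e2 <- simulate_event_train(0.2, 0.5, seed = 82)
  expect_identical(e1, e2)
})
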