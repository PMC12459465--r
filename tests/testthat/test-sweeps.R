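# Uncaging-locked sweep segmentation, normalization, averaging, peaks,
# and the paired channel comparison.

test_that("segmentation produces complete sweeps and drops the remainder", {
  m <- segment_sweeps(seq_len(400), frames_per_sweep = 16)
  expect_equal(nrow(m$values), 25L)        # 400 / 16
  expect_equal(m$values[2, ], 17:32)
  expect_equal(m$frames_per_sweep * m$frame_interval, 2.048)
  expect_warning(m17 <- segment_sweeps(seq_len(17), 16), "dropped 1")
  expect_equal(nrow(m17$values), 1L)
  expect_error(segment_sweeps(seq_len(10), 16), "shorter")
})

test_that("per-sweep normalization maps the first two frames to zero", {
  m <- segment_sweeps(rep(c(1, 1, 2, 2), 8), frames_per_sweep = 4)
  nm <- normalize_sweeps(m)
  expect_equal(unname(nm$values[1, ]), c(0, 0, 1, 1))
  # constant sweep -> all zeros
  mc <- normalize_sweeps(segment_sweeps(rep(5, 32), 16))
  expect_equal(max(abs(mc$values)), 0)
  # an injected step of amplitude a at frame 3 is recovered
  a <- 0.4
  v <- rep(10, 64)
  v[35:48] <- 10 * (1 + a)    # sweep 3, frames 3..16
  nm2 <- normalize_sweeps(segment_sweeps(v, 16))
  expect_equal(unname(nm2$values[3, 3]), a)
  # non-positive per-sweep baseline flagged, not silently used
  bad <- normalize_sweeps(segment_sweeps(c(rep(0, 16), rep(2, 16)), 16))
  expect_true(attr(bad$values, "invalid_sweeps")[1])
  expect_true(all(is.na(bad$values[1, ])))
})

test_that("pulse-to-sweep mapping selects sweeps 9 to 25 for pulses 2 to 18", {
  m <- sweep_matrix(matrix(rnorm(30 * 16), 30, 16), n_baseline_sweeps = 7L)
  av <- average_sweeps(m, pulses = 2:18)
  expect_equal(av$sweeps, 9:25)
  # frame-wise mean equals the direct column-mean oracle
  expect_equal(av$mean, colMeans(m$values[9:25, ]))
  expect_error(average_sweeps(m, pulses = 30), "sweep 37")
})

test_that("identical sweeps average to themselves with zero SEM", {
  row <- sin(seq_len(16))
  m <- sweep_matrix(matrix(rep(row, each = 20), 20, 16), n_baseline_sweeps = 0L)
  av <- average_sweeps(m, pulses = 1:20)
  expect_equal(av$mean, row)
  expect_equal(max(av$sem), 0)
})

test_that("normalization removes per-sweep affine scale", {
  set.seed(5)
  v <- rep(100, 160) + rnorm(160)
  m <- segment_sweeps(v, 16)
  base <- normalize_sweeps(m)$values
  gains <- runif(10, 0.5, 2)
  v2 <- as.numeric(t(matrix(v, 10, 16, byrow = TRUE) * gains))
  pert <- normalize_sweeps(segment_sweeps(v2, 16))$values
  expect_equal(pert, base, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("peak response averages the three post-pulse frames", {
  tr <- c(0, 0, 0.1, 0.2, 0.3, rep(0, 11))
  expect_equal(peak_response(tr, pulse_frame = 2), 0.2)
  expect_equal(peak_response(rep(0, 16)), 0)
  expect_error(peak_response(c(0, 0, 1), pulse_frame = 2), "too short")
  # slow-decaying synthetic release of amplitude a: peak close to a
  a <- 0.25
  t_in <- (0:15) * 0.128
  rel <- ifelse(t_in >= 2 * 0.128, a * exp(-(t_in - 2 * 0.128) / 5), 0)
  expect_lt(abs(peak_response(rel) - a), 0.1 * a)
  # and exactly the attenuated mean under the step-plus-decay model
  expect_equal(peak_response(rel),
               a * mean(exp(-c(0, 0.128, 0.256) / 5)))
})

test_that("paired comparison matches the textbook statistic and flags degeneracy", {
  a <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  b <- c(0.9, 0.7, 1.1, 1.0, 0.8)
  out <- paired_channel_comparison(a, b)
  # hand-computed: d = a-b, t = mean(d)/(sd(d)/sqrt(5)) = 2.236068
  expect_equal(out$statistic, 2.236068, tolerance = 1e-6)
  expect_equal(out$p.value, 0.089009, tolerance = 1e-5)
  ident <- paired_channel_comparison(b, b)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)
  deg <- paired_channel_comparison(c(1, 2, 3), c(0, 1, 2))
  expect_true(deg$degenerate)
  expect_error(paired_channel_comparison(1:4, 1:3), "equal length")
  expect_error(paired_channel_comparison(1:2, 2:3), "3 pairs")
})
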