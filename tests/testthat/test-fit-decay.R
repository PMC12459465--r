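# Mean arrival time, the closed-form binding-fraction estimator, and the
# Poisson maximum-likelihood decay fit.

mixture_mean_tau <- function(p_ad, tau_d, tau_ad) {
  ((1 - p_ad) * tau_d^2 + p_ad * tau_ad^2) /
    ((1 - p_ad) * tau_d + p_ad * tau_ad)
}

test_that("mean arrival time recovers the lifetime of a pure exponential", {
  h <- simulate_photon_histogram(
    decay_params(p_ad = 0, tau_d = 2.6, tau_ad = 1.3, tau_g = 1e-6, t0 = 0),
    n_photons = 2e5, period = 40, seed = 11)
  expect_equal(mean_arrival_time(h), 2.6, tolerance = 0.02)
})

test_that("mean arrival time is translation-equivariant and scale-invariant", {
  h <- simulate_photon_histogram(
    decay_params(p_ad = 0.3, tau_ad = 1.3, tau_g = 0.2, t0 = 0.5),
    n_photons = 5e4, seed = 12)
  m0 <- mean_arrival_time(h)
  shifted <- photon_histogram(h$bin_edges + 1.0, h$counts, h$period + 1.0)
  expect_equal(mean_arrival_time(shifted), m0 + 1.0, tolerance = 1e-12)
  scaled <- photon_histogram(h$bin_edges, h$counts * 7, h$period)
  expect_equal(mean_arrival_time(scaled), m0, tolerance = 1e-12)
  empty <- photon_histogram(h$bin_edges, h$counts * 0, h$period)
  expect_error(mean_arrival_time(empty), "no photons")
})

test_that("mean arrival time of a mixture matches the photon-weighted closed form", {
  h <- simulate_photon_histogram(
    decay_params(p_ad = 0.3, tau_ad = 1.3, tau_g = 1e-6, t0 = 0),
    n_photons = 5e5, period = 40, seed = 13)
  expect_equal(mean_arrival_time(h), 2.370588, tolerance = 0.01)
})

test_that("binding fraction estimator hits the trivial endpoints", {
  expect_equal(as.numeric(binding_fraction_from_mean(2.6, 2.6, 1.3)), 0)
  expect_equal(as.numeric(binding_fraction_from_mean(1.3, 2.6, 1.3)), 1)
  expect_equal(as.numeric(binding_fraction_from_mean(2.370588, 2.6, 1.3)),
               0.3, tolerance = 1e-5)
})

test_that("binding fraction inversion is exact over random parameter draws", {
  set.seed(42)
  for (i in 1:200) {
    tau_d <- runif(1, 1, 4)
    tau_ad <- runif(1, 0.2, 0.95) * tau_d
    p <- runif(1)
    mt <- mixture_mean_tau(p, tau_d, tau_ad)
    expect_equal(as.numeric(binding_fraction_from_mean(mt, tau_d, tau_ad)),
                 p, tolerance = 1e-12)
  }
})

test_that("out-of-range estimates are flagged, clipped only on request", {
  p <- binding_fraction_from_mean(2.7, 2.6, 1.3)
  expect_lt(as.numeric(p), 0)
  expect_true(attr(p, "out_of_range"))
  pc <- binding_fraction_from_mean(2.7, 2.6, 1.3, clip = TRUE)
  expect_equal(as.numeric(pc), 0)
  expect_true(attr(pc, "out_of_range"))
  expect_error(binding_fraction_from_mean(3.9, 2.6, 1.3), "degenerate")
  expect_error(binding_fraction_from_mean(2, 1.3, 2.6), "smaller")
})

test_that("decay fit recovers simulated parameters and keeps tau_d fixed", {
  truth <- decay_params(p_ad = 0.3, tau_ad = 1.3, tau_g = 0.2, t0 = 1)
  h <- simulate_photon_histogram(truth, 3e5, seed = 21)
  ft <- fit_decay(h, tau_d_fixed = 2.6)
  expect_true(ft$converged)
  expect_identical(ft$params$tau_d, 2.6)
  expect_equal(ft$params$p_ad, 0.3, tolerance = 0.03)
  expect_equal(ft$params$tau_ad, 1.3, tolerance = 0.1)
  expect_equal(ft$params$t0, 1, tolerance = 0.05)
  # fit and closed-form estimator agree on p_ad
  cf <- binding_fraction_from_mean(mean_arrival_time(h) - ft$params$t0,
                                   2.6, ft$params$tau_ad)
  expect_equal(ft$params$p_ad, as.numeric(cf), tolerance = 0.03)
})

test_that("pure-donor histograms fit to a near-zero binding fraction", {
  h <- simulate_photon_histogram(
    decay_params(p_ad = 0, tau_ad = 1.3, tau_g = 0.2, t0 = 1), 1e6, seed = 22)
  ft <- fit_decay(h)
  expect_lt(ft$params$p_ad, 0.02)
})

test_that("photon floor and WLS fallback behave", {
  truth <- decay_params(p_ad = 0.3, tau_ad = 1.3, tau_g = 0.2, t0 = 1)
  small <- simulate_photon_histogram(truth, 500, seed = 23)
  expect_error(fit_decay(small), "insufficient photons")
  h <- simulate_photon_histogram(truth, 1e5, seed = 24)
  ft <- fit_decay(h, method = "wls")
  expect_equal(ft$params$p_ad, 0.3, tolerance = 0.05)
})

test_that("QC filter keeps cells at or below the 0.45 baseline threshold", {
  cells <- c(a = 0.44, b = 0.46, c = 0.45, d = 0.10)
  kept <- qc_filter_cells(cells)
  expect_named(kept, c("a", "c", "d"))
  expect_equal(attr(kept, "keep"), c(TRUE, FALSE, TRUE, TRUE),
               ignore_attr = TRUE)
  expect_length(qc_filter_cells(cells, threshold = 0.2), 1L)
  expect_error(qc_filter_cells(cells, threshold = 0), "threshold")
})
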