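test_that("the scale grid covers every analysis band", {
  freqs <- cmc_scales()
  defs <- band_definitions()
  for (i in seq_len(nrow(defs))) {
    expect_true(any(freqs >= defs$lo[i] & freqs <= defs$hi[i]),
                info = defs$band[i])
  }
  expect_true(all(diff(freqs) < 0))
})

test_that("self-coherence is 1 and the ratio is smoothing-driven", {
  set.seed(2)
  x <- rnorm(5000)
  res <- wavelet_coherence(x, x, fs = 250)
  valid <- outer(res$freqs, res$coi, ">=")
  expect_lt(max(abs(res$coherence[valid] - 1)), 1e-6)

  # without smoothing the magnitude-coherence ratio is identically 1
  raw <- wavelet_coherence(x, rnorm(5000), fs = 250, smooth = FALSE)
  expect_lt(max(abs(raw$coherence - 1), na.rm = TRUE), 1e-9)
})

test_that("coherence is symmetric and amplitude-invariant", {
  set.seed(3)
  pr <- generate_coupled_pair(2, c(8, 30), rng_seed = 3)
  a <- wavelet_coherence(pr$x, pr$y)
  b <- wavelet_coherence(pr$y, pr$x)
  expect_equal(a$coherence, b$coherence, tolerance = 1e-10)

  scaled <- wavelet_coherence(
    uniform_series(37 * pr$x$values, 250),
    uniform_series(-0.013 * pr$y$values, 250))
  expect_equal(a$coherence, scaled$coherence, tolerance = 1e-8)

  expect_error(wavelet_coherence(rnorm(100), rnorm(101), fs = 250),
               "equal length")
  expect_error(wavelet_coherence(uniform_series(rnorm(100), 250),
                                 uniform_series(rnorm(100), 200)),
               "sampling rate")
})

test_that("a small delay spares slow bands and degrades gamma", {
  pr <- generate_coupled_pair(Inf, c(2, 49), rng_seed = 5)
  x <- pr$x$values
  y <- c(rep(0, 5), x[1:(length(x) - 5)])  # 20 ms delay at 250 Hz
  ba <- bin_average(wavelet_coherence(x, y, fs = 250))
  theta <- band_average(ba, "theta")
  gamma <- band_average(ba, "gamma")
  expect_gt(theta, 0.95)
  expect_lt(gamma, 0.9)
  expect_gt(theta, gamma)
})

test_that("bin averaging yields 9 bins with edge bins excluded", {
  set.seed(6)
  res <- wavelet_coherence(rnorm(5000), rnorm(5000), fs = 250)
  kept <- bin_average(res)
  expect_equal(attr(kept, "n_bins_total"), 9)
  expect_equal(ncol(kept), 7)
  expect_equal(attr(kept, "bins_kept"), 2:8)
  all9 <- bin_average(res, drop_edges = FALSE)
  expect_equal(ncol(all9), 9)

  # constant coherence: every usable (non-fully-masked) bin mean equals
  # the constant
  res$coherence[] <- 0.42
  cst <- bin_average(res)
  expect_true(all(abs(cst[!is.na(cst)] - 0.42) < 1e-12))
  expect_gt(mean(!is.na(cst)), 0.7)

  # time ramp: bin means equal the analytic bin-centre values where the
  # whole bin is inside the COI
  n <- ncol(res$coherence)
  res$coherence <- matrix(rep(seq(0, 1, length.out = n), each = nrow(res$coherence)),
                          nrow = nrow(res$coherence))
  res$coi <- rep(0, n)  # disable masking for the arithmetic check
  bins <- bin_average(res, drop_edges = FALSE)
  centres <- (seq_len(9) - 0.5) * 500
  expect_equal(unname(bins[1, ]), (centres - 1) / (n - 1), tolerance = 1e-3)

  short <- res
  short$coherence <- short$coherence[, 1:4499]
  short$coi <- short$coi[1:4499]
  expect_error(bin_average(short), "divisible")
})

test_that("band averaging uses in-band in-COI cells only", {
  freqs <- cmc_scales()
  m <- matrix(0, length(freqs), 7)
  beta_rows <- freqs >= 12 & freqs <= 30
  m[beta_rows, ] <- 1
  expect_equal(band_average(m, "beta", freqs = freqs), 1)
  expect_equal(band_average(m, "theta", freqs = freqs), 0)
  expect_equal(band_average(m, "gamma", freqs = freqs), 0)

  m2 <- matrix(0.3, length(freqs), 7)
  for (b in band_definitions()$band) {
    expect_equal(band_average(m2, b, freqs = freqs), 0.3)
  }
  expect_error(band_average(m2, c(200, 300), freqs = freqs), "no scale")
})

test_that("fisher z is the clipped arc hyperbolic tangent", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(0.07), atanh(0.07))
  expect_equal(fisher_z(0.07), 0.07011466, tolerance = 1e-6)
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(-0.1), "0, 1")
  expect_error(fisher_z(1.5), "0, 1")
  expect_true(all(diff(fisher_z(seq(0, 0.99, 0.01))) > 0))
})

test_that("the closed-form significance threshold matches its formula", {
  expect_equal(significance_threshold(42, 0.05), 1 - 0.05^(1 / 41))
  expect_equal(round(significance_threshold(42, 0.05), 2), 0.07)
  expect_equal(significance_threshold(2, 0.05), 0.95)
  expect_equal(significance_threshold(11, 0.05), 0.2589, tolerance = 2e-4)
  expect_error(significance_threshold(1), ">= 2")
  expect_error(significance_threshold(42, 0), "alpha")
  expect_error(significance_threshold(42, 1), "alpha")
})

test_that("segment-pooled coherence behaves at its extremes", {
  set.seed(9)
  xs <- lapply(1:3, function(i) rnorm(5000))
  pc <- pooled_band_coherence(xs, xs, fs = 250)
  expect_true(all(pc$coherence[pc$n_segments > 0] > 0.999))
  expect_equal(max(pc$n_segments), 3 * 7)
})

test_that("Monte Carlo thresholds match the closed form for white noise", {
  freqs <- cmc_scales()[which.min(abs(cmc_scales() - 20))]
  set.seed(10)
  x <- rnorm(5000)
  y <- rnorm(5000)
  thr <- monte_carlo_significance(x, y, fs = 250, n_iter = 150,
                                  freqs = freqs, seed = 2)
  # pooled estimator over 7 usable bins: Goodman null, threshold Z(7)
  expect_equal(thr$threshold, significance_threshold(7, 0.05),
               tolerance = 0.12)

  thr_small <- monte_carlo_significance(x, y, fs = 250, n_iter = 60,
                                        freqs = freqs, seed = 3)
  # a 60-draw 95th-percentile estimate is noisy; agreement within its
  # quantile sampling error (~0.1 on this scale)
  expect_equal(thr$threshold, thr_small$threshold, tolerance = 0.3)

  thr1 <- monte_carlo_significance(x, y, fs = 250, n_iter = 50,
                                   freqs = freqs, alpha = 1)
  expect_equal(thr1$threshold, 0)
})

test_that("coherence results serialise with their sidecar", {
  set.seed(12)
  res <- wavelet_coherence(rnorm(2500), rnorm(2500), fs = 250,
                           window_s = 10)
  base <- tempfile("coh")
  write_coherence(res, base)
  back <- read_coherence(base)
  expect_equal(back$coherence, res$coherence, tolerance = 1e-12)
  expect_equal(back$freqs, res$freqs)
  expect_equal(back$fs, res$fs)
  unlink(paste0(base, c(".csv.gz", ".json")))

  expect_equal(effective_segments(6), 42)
  expect_equal(effective_segments(4), 28)
})

test_that("the cone of influence tightens towards the window edges", {
  coi <- cmcmarkers:::coi_frequencies(4500, 250)
  expect_true(is.infinite(coi[1]))
  mid <- coi[2250]
  expect_lt(mid, coi[100])
  expect_equal(coi[100], coi[4401])  # symmetric
})
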