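test_that("gain-to-difficulty mapping is deterministic and total", {
  expect_equal(difficulty_of_gain(c(0, 0.6, -0.4, 0, 1.0, -1.0)),
               c("low", "medium", "high", "low", "medium", "high"))
  expect_error(difficulty_of_gain(2), "unknown gain")
})

test_that("ground truth respects its invariants", {
  truth <- ground_truth(3)
  combos <- expand.grid(muscle = c("BF", "RF", "TA", "GM", "SOL"),
                        side = c("AD", "LN"),
                        band = band_definitions()$band,
                        difficulty = c("low", "medium", "high"),
                        group = c("stroke", "healthy"),
                        stringsAsFactors = FALSE)
  snr <- mapply(function(m, s, b, d, g) coupling_snr(truth, m, s, b, d, g),
                combos$muscle, combos$side, combos$band, combos$difficulty,
                combos$group)
  expect_true(all(snr >= 0))
  # stroke affected side strictly weaker than less-affected for at least
  # one (muscle, band) pair, inducing measurable asymmetry
  ad <- coupling_snr(truth, "SOL", "AD", "theta", "medium", "stroke")
  ln <- coupling_snr(truth, "SOL", "LN", "theta", "medium", "stroke")
  expect_lt(ad, ln)
  expect_true(all(truth$missing_prob$prob >= 0 & truth$missing_prob$prob <= 1))
})

test_that("coupled pairs share a band-limited source with snr-driven coherence", {
  expect_error(generate_coupled_pair(1, c(12, 130), fs_x = 250, fs_y = 250),
               "Nyquist")
  expect_error(generate_coupled_pair(-1, c(12, 30)), "non-negative")

  # noise-free copies: in-band coherence is (numerically) 1
  pr <- generate_coupled_pair(Inf, c(12, 30), rng_seed = 4)
  ba <- bin_average(wavelet_coherence(pr$x, pr$y))
  expect_gt(band_average(ba, "beta"), 0.999)

  # higher snr gives higher estimated band coherence
  cmc_of <- function(snr) {
    pr <- generate_coupled_pair(snr, c(12, 30), rng_seed = 7)
    band_average(bin_average(wavelet_coherence(pr$x, pr$y)), "beta")
  }
  expect_lt(cmc_of(0.5), cmc_of(5))

  # determinism: identical seeds give bit-identical signals
  a <- generate_coupled_pair(2, c(4, 8), rng_seed = 9)
  b <- generate_coupled_pair(2, c(4, 8), rng_seed = 9)
  expect_identical(a$x$values, b$x$values)
  expect_identical(a$y$values, b$y$values)
})

test_that("coupled pairs support different sampling rates", {
  pr <- generate_coupled_pair(5, c(4, 8), fs_x = 250, fs_y = 10000 / 9,
                              rng_seed = 2)
  expect_equal(length(pr$x), 5000)
  expect_equal(length(pr$y), 22222)
})

test_that("cop traces scale with difficulty and group", {
  truth <- ground_truth(1)
  # degenerate amplitude: zero sway scale gives constant zero traces
  t0 <- truth
  t0$sway_scale$ap <- 0
  t0$sway_scale$ml <- 0
  tr <- generate_cop_trace("high", "stroke", rng_seed = 1, truth = t0)
  expect_true(all(tr$ap == 0) && all(tr$ml == 0))

  # determinism
  a <- generate_cop_trace("low", "healthy", rng_seed = 5, truth = truth)
  b <- generate_cop_trace("low", "healthy", rng_seed = 5, truth = truth)
  expect_identical(a$ml, b$ml)

  # stroke/high ML sway exceeds healthy/low ML sway in nearly all seeds
  wins <- vapply(1:60, function(s) {
    hi <- generate_cop_trace("high", "stroke", rng_seed = s, truth = truth)
    lo <- generate_cop_trace("low", "healthy", rng_seed = s + 1000,
                             truth = truth)
    sqrt(mean((hi$ml - mean(hi$ml))^2)) > sqrt(mean((lo$ml - mean(lo$ml))^2))
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("cohorts have the study's structure", {
  coh <- tiny_cohort(2, 2, seed = 21)
  expect_s3_class(coh, "cmc_cohort")
  expect_equal(nrow(coh), 4)
  expect_equal(coh$group, c("stroke", "stroke", "healthy", "healthy"))
  # no missingness: exactly 6 trials in the printed gain order
  for (trials in coh$trials) {
    expect_length(trials, 6)
    expect_equal(vapply(trials, `[[`, numeric(1), "gain"),
                 c(0, 0.6, -0.4, 0, 1.0, -1.0))
    for (tr in trials) {
      expect_equal(tr$difficulty, difficulty_of_gain(tr$gain))
      expect_length(tr$eeg, 5000)
      expect_length(tr$emg, 10)
      expect_length(tr$emg[[1]], 22222)
      expect_length(tr$cop_ap, 2000)
      expect_true(all(is.finite(tr$eeg)))
    }
  }
  expect_true(all(coh$bbs >= 0 & coh$bbs <= 56))
  expect_true(all(coh$tug > 0))

  # empty cohort
  expect_equal(nrow(simulate_cohort(0, 0, truth = ground_truth(1))), 0)

  # determinism: identical truth (incl. seed) gives identical cohorts
  a <- simulate_cohort(1, 1, truth = ground_truth(33))
  b <- simulate_cohort(1, 1, truth = ground_truth(33))
  expect_identical(a$bbs, b$bbs)
  expect_identical(a$tug, b$tug)
  expect_identical(a$trials[[1]][[1]]$eeg, b$trials[[1]][[1]]$eeg)
  expect_identical(a$trials[[2]][[2]]$emg, b$trials[[2]][[2]]$emg)
})

test_that("cohorts round-trip through the on-disk layout", {
  coh <- simulate_cohort(1, 0, truth = ground_truth(8))
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subject_id, coh$subject_id)
  expect_equal(back$bbs, coh$bbs)
  expect_equal(length(back$trials[[1]]), length(coh$trials[[1]]))
  tr0 <- coh$trials[[1]][[1]]
  tr1 <- back$trials[[1]][[1]]
  expect_equal(tr1$gain, tr0$gain)
  expect_equal(tr1$fs_emg, tr0$fs_emg, tolerance = 1e-8)
  expect_equal(tr1$eeg, tr0$eeg, tolerance = 1e-12)
  expect_equal(tr1$emg[["TA.AD"]], tr0$emg[["TA.AD"]], tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
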