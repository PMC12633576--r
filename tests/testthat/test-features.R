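test_that("asymmetry and task-modulation indices follow the shared formula", {
  expect_equal(asymmetry_index(0.4, 0.4), 0)
  expect_equal(asymmetry_index(0.7, 0), 1)
  expect_equal(asymmetry_index(0, 0.2), -1)
  expect_equal(asymmetry_index(0.6, 0.2), 0.5)
  expect_equal(task_modulation_index(0.3, 0.1), 0.5)
  expect_equal(task_modulation_index(0.5, 0.5), 0)
  expect_true(is.na(asymmetry_index(0, 0)))
  expect_error(asymmetry_index(-0.1, 0.2), "non-negative")

  # antisymmetry under argument swap
  set.seed(1)
  a <- runif(50)
  b <- runif(50)
  expect_equal(asymmetry_index(a, b), -asymmetry_index(b, a))
  expect_true(all(abs(asymmetry_index(a, b)) <= 1))
})

test_that("band AUC is a trapezoidal integral with additivity", {
  f <- seq(12, 30, by = 0.5)
  expect_equal(band_auc(f, rep(0.6, length(f)), "beta"), 0.6 * 18)

  # two-point trapezoid by hand
  expect_equal(band_auc(c(14, 20), c(0.2, 0.8), "beta"),
               (0.2 + 0.8) * 6 / 2)

  # additivity over contiguous sub-bands split at a grid point
  set.seed(2)
  cvals <- runif(length(f))
  whole <- band_auc(f, cvals, c(12, 30))
  expect_equal(whole, band_auc(f, cvals, c(12, 20)) +
                 band_auc(f, cvals, c(20, 30)))

  expect_error(band_auc(c(15), c(0.5), "beta"), "two in-band")
  # descending grids (wavelet order) integrate identically
  expect_equal(band_auc(rev(f), rev(cvals), "beta"), whole)
})

test_that("sample entropy matches the brute-force template counter", {
  set.seed(7)
  x <- as.numeric(arima.sim(list(ar = 0.6), 200))
  expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 0)

  # constant series: 0 by convention
  expect_equal(sample_entropy(rep(2, 100)), 0)

  # perfectly periodic alternating series: every matching template stays
  # matching, so the entropy is exactly 0 (and equals the oracle tally)
  alt <- rep(c(1, -1), 30)
  expect_equal(sample_entropy(alt), 0)
  expect_equal(sample_entropy(alt), sampen_oracle(alt))

  # irregular signals are more entropic than regular ones
  set.seed(8)
  noise <- rnorm(300)
  sine <- sin(2 * pi * 3 * (0:299) / 100) * sd(noise) / sqrt(0.5)
  expect_gt(sample_entropy(noise), sample_entropy(sine))

  expect_error(sample_entropy(rnorm(20)), "50")
})

test_that("cop_summary returns the five sway statistics", {
  fs <- 100
  t <- (0:1999) / fs
  s <- cop_summary(1.5 * sin(2 * pi * 1 * t), fs = fs, direction = "ML")
  expect_equal(s$rms, 1.5 / sqrt(2), tolerance = 0.01)
  expect_equal(s$mean, 0, tolerance = 1e-10)
  # mean absolute velocity of a sine: (2/pi) * 2*pi*f*A = 4*f*A
  expect_equal(s$velocity, 4 * 1 * 1.5, tolerance = 0.02)

  cst <- cop_summary(rep(0.7, 200), fs = fs)
  expect_equal(cst$mean, 0.7)
  expect_equal(cst$std, 0)
  expect_equal(cst$rms, 0)
  expect_equal(cst$velocity, 0)
  expect_equal(cst$entropy, 0)
  expect_error(cop_summary(rnorm(50), fs = fs), "100")
})

test_that("95% confidence ellipse area matches its closed form", {
  # collinear trajectory: degenerate covariance
  expect_warning(a0 <- ellipse_area_95(1:10, 2 * (1:10)), "degenerate")
  expect_equal(a0, 0)

  # isotropic unit variance: area -> pi * 5.991
  set.seed(3)
  n <- 20000
  ap <- rnorm(n)
  ml <- rnorm(n)
  expect_equal(ellipse_area_95(ap, ml), pi * qchisq(0.95, 2),
               tolerance = 0.03)

  # coverage: the fitted ellipse contains ~95% of draws from a correlated
  # Gaussian
  sig <- matrix(c(1, 0.6, 0.6, 2), 2)
  L <- chol(sig)
  z <- matrix(rnorm(2 * 50000), ncol = 2) %*% L
  S <- stats::cov(z)
  md <- stats::mahalanobis(z, colMeans(z), S)
  expect_equal(mean(md <= qchisq(0.95, 2)), 0.95, tolerance = 0.005)
})

test_that("path-length features summarise the increment series", {
  # straight line from (0,0) to (3,4): total path length 5
  ap <- seq(0, 3, length.out = 6)
  ml <- seq(0, 4, length.out = 6)
  pl <- path_length_features(ap, ml)
  expect_equal(pl$total, 5)
  expect_equal(pl$std, 0)
  expect_equal(pl$entropy, 0)

  cst <- path_length_features(rep(1, 10), rep(2, 10))
  expect_true(all(unlist(cst) == 0))

  # unit square traversal over 5 points
  sq <- path_length_features(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(sq$total, 4)
  expect_equal(sq$mean, 1)
  expect_equal(sq$rms, 1)

  # time-reversal invariance of path length and increment RMS
  set.seed(4)
  ap2 <- cumsum(rnorm(300))
  ml2 <- cumsum(rnorm(300))
  fwd <- path_length_features(ap2, ml2)
  rev_ <- path_length_features(rev(ap2), rev(ml2))
  expect_equal(fwd$total, rev_$total)
  expect_equal(fwd$rms, rev_$rms)
})

test_that("the registry enumerates the 528-column schema", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 528)
  expect_equal(anyDuplicated(reg$name), 0)
  counts <- table(reg$family)
  expect_equal(as.numeric(counts[c("CMC", "AI", "TMI", "AUC")]),
               c(150, 75, 100, 150))
  expect_equal(as.numeric(counts[c("COP-AP", "COP-ML", "COP-PL",
                                   "EllipseArea")]),
               c(15, 15, 15, 3))
  expect_equal(as.numeric(counts[c("subject", "group", "age", "BBS",
                                   "TUG")]),
               rep(1, 5))
  # combinatorial structure: 3 conditions x 2 sides x 5 muscles x 5 bands
  cmc <- reg[reg$family == "CMC", ]
  expect_equal(nrow(unique(cmc[c("muscle", "side", "band", "condition")])),
               150)
})

test_that("feature extraction fills the schema for a complete cohort", {
  coh <- tiny_cohort(2, 2, seed = 11)
  ft <- extract_features(coh)
  expect_equal(dim(ft), c(4, 528))
  expect_equal(names(ft), feature_registry()$name)
  expect_equal(sum(is.na(ft)), 0)
  expect_equal(ft$group, c(0, 0, 1, 1))
  expect_equal(ft$bbs, as.numeric(coh$bbs))
  expect_true(all(ft$CMC_TA_AD_delta_medcomb >= 0))

  # single-subject cohort: one full row
  one <- extract_features(simulate_cohort(1, 0, truth = ground_truth(12)))
  expect_equal(dim(one), c(1, 528))

  # composite columns agree with the shared formula applied to CMC columns
  ai <- asymmetry_index(ft$CMC_SOL_AD_theta_medcomb,
                        ft$CMC_SOL_LN_theta_medcomb)
  expect_equal(ft$AI_SOL_theta_medcomb, ai)
  tmi <- task_modulation_index(ft$CMC_RF_LN_beta_highcomb,
                               ft$CMC_RF_LN_beta_medcomb)
  expect_equal(ft$TMI_RF_LN_beta_HM, tmi)
})

test_that("extraction is deterministic and missing trials yield NA blocks", {
  coh <- simulate_cohort(1, 1, truth = ground_truth(19))
  a <- extract_features(coh)
  b <- extract_features(coh)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # drop the whole high condition of subject 1 -> its high features are NA
  coh2 <- coh
  keep <- vapply(coh2$trials[[1]], function(tr) tr$difficulty != "high",
                 logical(1))
  coh2$trials[[1]] <- coh2$trials[[1]][keep]
  ft <- extract_features(coh2)
  expect_true(is.na(ft$CMC_TA_AD_delta_highcomb[1]))
  expect_true(is.na(ft$COP_ML_rms_highcomb[1]))
  expect_true(is.na(ft$TMI_TA_AD_delta_HM[1]))   # needs the high condition
  expect_false(is.na(ft$TMI_TA_AD_delta_ML[1]))  # medium-low unaffected
  expect_false(is.na(ft$CMC_TA_AD_delta_medcomb[1]))
})

test_that("stratified KNN imputation recovers nearest-donor structure", {
  # hand-built single-group table: 4 rows, 2 informative columns
  tbl <- tibble::tibble(
    group = c(0, 0, 0, 0),
    f1 = c(1.0, 1.1, 5.0, 9.0),
    f2 = c(NA, 1.0, 5.2, 9.1),
    f3 = c(2.0, 2.1, 6.0, 10.0)
  )
  # k = 1: row 2 is the closest donor (f1/f3 nearly identical)
  imp1 <- suppressWarnings(impute_features(tbl, k_grid = 1))
  expect_equal(imp1$data$f2[1], 1.0)
  # k = 3: mean of the three donors
  imp3 <- suppressWarnings(impute_features(tbl, k_grid = 3))
  expect_equal(imp3$data$f2[1], mean(c(1.0, 5.2, 9.1)))
  # k larger than the donor pool: capped with a warning
  expect_warning(impute_features(tbl, k_grid = 9), "capped")

  # imputed values stay inside the donor range
  set.seed(5)
  big <- tibble::tibble(group = rep(c(0, 1), each = 8))
  for (j in 1:5) big[[paste0("g", j)]] <- rnorm(16, mean = big$group * 3)
  holes <- big
  holes$g1[c(2, 10)] <- NA
  holes$g3[5] <- NA
  imp <- impute_features(holes, k_grid = c(1, 3, 5))
  expect_equal(sum(is.na(imp$data)), 0)
  g0 <- big$group == 0
  expect_true(imp$data$g1[2] >= min(holes$g1[g0], na.rm = TRUE) &&
                imp$data$g1[2] <= max(holes$g1[g0], na.rm = TRUE))

  # no missing data: table unchanged, zero deviation, tie-break to max k
  full <- impute_features(big, k_grid = c(1, 3, 5, 7))
  expect_equal(as.data.frame(full$data), as.data.frame(big))
  expect_equal(full$chosen_k, 7)
  expect_true(all(full$deviation_report$n_deviating == 0))
  expect_equal(tidy(full), full$deviation_report)

  # a column entirely missing within a group is an error
  bad <- big
  bad$g2[bad$group == 0] <- NA
  expect_error(suppressWarnings(impute_features(bad, k_grid = 1)),
               "entirely missing")
})
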