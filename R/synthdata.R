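# Synthetic cohort generator: band-limited coupled EEG/EMG sources, Ornstein-
# Uhlenbeck sway traces, and outcome scores generated from named ground-truth
# features, so the whole downstream pipeline is testable without any
# recordings.

MUSCLES <- c("BF", "RF", "TA", "GM", "SOL")
SIDES <- c("AD", "LN")  # AD: affected (stroke) / dominant (healthy);
                        # LN: less-affected / nondominant
CONDITIONS <- c(low = "lowcomb", medium = "medcomb", high = "highcomb")
TRIAL_GAINS <- c(0, 0.6, -0.4, 0, 1.0, -1.0)

#' Map a platform sway gain to its difficulty class
#'
#' Gain 0 (fixed surface) is low difficulty; positive gains 0.6 and 1.0 are
#' medium; negative gains -0.4 and -1.0 (surface opposing sway) are high.
#'
#' @param gain Numeric vector of sway-referencing gains.
#' @return Character vector in `c("low", "medium", "high")`.
#' @export
difficulty_of_gain <- function(gain) {
  out <- rep(NA_character_, length(gain))
  out[gain == 0] <- "low"
  out[gain %in% c(0.6, 1.0)] <- "medium"
  out[gain %in% c(-0.4, -1.0)] <- "high"
  if (anyNA(out)) stop("unknown gain value(s): ",
                       paste(unique(gain[is.na(out)]), collapse = ", "))
  out
}

#' Ground-truth parameters of the synthetic cohort
#'
#' Bundles every knob of the generator: per-(muscle, side, band, difficulty,
#' group) corticomuscular coupling strength (in-band source-to-noise
#' variance ratio), sway amplitudes (cm) by difficulty and direction,
#' trial-missingness probabilities (falls), and the linear weights that
#' generate BBS/TUG from named ground-truth features. Each muscle couples
#' in one characteristic band (TA delta, SOL theta, GM/RF/BF beta); stroke
#' subjects have a four-fold reduced coupling on the affected side, a
#' compensatory increase on the less-affected side, and a drop in coupling
#' under high difficulty, which induces the asymmetry and task-modulation
#' contrasts the composite indices measure.
#'
#' @param seed Integer seed stored with the truth; [simulate_cohort()]
#'   defaults to it.
#' @return A `cmc_ground_truth` object (a named list).
#' @export
ground_truth <- function(seed = 1L) {
  truth <- list(
    base_snr = c(low = 2, medium = 4, high = 3),
    side_mult = c(AD = 1, LN = 0.85),
    # stroke deficits are concentrated: each affected muscle expresses its
    # group effect in one condition (a 4-fold affected-side drop and, for
    # the asymmetry muscles, a compensatory less-affected increase); GM is
    # a no-effect control muscle
    stroke_overrides = tibble::tibble(
      muscle = c("TA", "SOL", "SOL", "BF", "BF", "RF", "RF"),
      side = c("AD", "AD", "LN", "AD", "LN", "LN", "LN"),
      difficulty = c("medium", "medium", "medium", "high", "high",
                     "high", "medium"),
      mult = c(0.25, 0.30, 1.30, 0.30, 1.30, 0.25, 1.30)
    ),
    active_bands = c(TA = "delta", GM = "beta", SOL = "theta",
                     RF = "beta", BF = "beta"),
    subject_sd = 0.2, channel_sd = 0.15,
    sway_scale = tibble::tibble(
      difficulty = c("low", "medium", "high"),
      ap = c(0.35, 0.55, 0.80),
      ml = c(0.25, 0.40, 0.55)
    ),
    sway_stroke_ml_high = 2.6,
    sway_subject_sd = 0.2,
    cop_tau = 1.0, cop_offset_sd = 0.3,
    missing_prob = tibble::tibble(
      group = rep(c("stroke", "healthy"), each = 3),
      difficulty = rep(c("low", "medium", "high"), 2),
      prob = c(0.03, 0.10, 0.25, 0.01, 0.03, 0.08)
    ),
    outcome = list(
      bbs = list(intercept = 2.0, noise_sd = 0.25,
                 weights = c(AUC_TA_AD_delta_medcomb = 0.33,
                             AI_SOL_theta_medcomb = 0.27,
                             COP_ML_rms_highcomb = -0.30)),
      tug = list(intercept = 2.7, noise_sd = 0.12,
                 weights = c(AI_BF_beta_highcomb = -0.25,
                             COP_ML_rms_highcomb = 0.15,
                             AUC_TA_AD_delta_medcomb = -0.12,
                             TMI_RF_LN_beta_HM = -0.15))
    ),
    feature_scaling = tibble::tibble(
      feature = c("AUC_TA_AD_delta_medcomb", "AI_SOL_theta_medcomb",
                  "COP_ML_rms_highcomb", "AI_BF_beta_highcomb",
                  "TMI_RF_LN_beta_HM"),
      center = c(2.36, -0.30, 0.98, -0.30, -0.47),
      scale = c(1.50, 0.36, 0.47, 0.36, 0.30)
    ),
    age = list(stroke = c(mean = 60.9, sd = 9.17, lo = 37, hi = 70),
               healthy = c(mean = 57.2, sd = 7.98, lo = 35, hi = 70)),
    seed = as.integer(seed)
  )
  validate_ground_truth(truth)
  structure(truth, class = "cmc_ground_truth")
}

validate_ground_truth <- function(truth) {
  if (any(truth$base_snr < 0) || any(truth$side_mult < 0) ||
      any(truth$stroke_overrides$mult < 0)) {
    stop("coupling_snr components must be non-negative")
  }
  if (any(truth$missing_prob$prob < 0 | truth$missing_prob$prob > 1)) {
    stop("missing_prob must lie in [0, 1]")
  }
  invisible(truth)
}

#' @export
print.cmc_ground_truth <- function(x, ...) {
  cat("<cmc_ground_truth>\n")
  cat("  base snr by difficulty:",
      paste(names(x$base_snr), x$base_snr, sep = "=", collapse = " "), "\n")
  cat("  active bands:",
      paste(names(x$active_bands), x$active_bands, sep = "-",
            collapse = " "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Coupling strength for a muscle/side/band/difficulty/group cell
#'
#' @param truth A [ground_truth()] object.
#' @param muscle One of BF, RF, TA, GM, SOL.
#' @param side `"AD"` or `"LN"`.
#' @param band Frequency band name.
#' @param difficulty `"low"`, `"medium"` or `"high"`.
#' @param group `"stroke"` or `"healthy"`.
#' @return Non-negative in-band source-to-noise variance ratio (0 when the
#'   muscle does not couple in that band).
#' @export
coupling_snr <- function(truth, muscle, side, band, difficulty, group) {
  stopifnot(inherits(truth, "cmc_ground_truth"))
  if (truth$active_bands[[muscle]] != band) return(0)
  mult <- truth$side_mult[[side]]
  if (group == "stroke") {
    ov <- truth$stroke_overrides
    hit <- ov$muscle == muscle & ov$side == side & ov$difficulty == difficulty
    if (any(hit)) mult <- ov$mult[hit][1]
  }
  truth$base_snr[[difficulty]] * mult
}

# Draw a band-limited unit-variance Gaussian source as random Fourier
# coefficients on a 0.05 Hz grid, synthesised coherently at 250 Hz and
# (optionally) at an auxiliary rate. Consumes the current RNG stream.
bl_source_coeffs <- function(band, duration) {
  df <- 1 / duration
  k <- seq(max(1, ceiling(band[1] / df)), floor(band[2] / df))
  list(k = k, z = complex(real = rnorm(length(k)), imaginary = rnorm(length(k))),
       df = df)
}

bl_source_render <- function(coeffs, fs, n) {
  # render on an FFT-friendly grid at >= fs covering the same duration,
  # then interpolate onto the requested grid
  duration <- n / fs
  # pick a 5-smooth length >= n for fast FFT; the coefficient grid spacing
  # 1/duration is preserved exactly
  n_use <- next_fast_len(n)
  spec <- complex(length.out = n_use)
  keep <- coeffs$k < n_use / 2
  kk <- coeffs$k[keep]
  spec[kk + 1] <- coeffs$z[keep]
  spec[n_use - kk + 1] <- Conj(coeffs$z[keep])
  src <- Re(fft(spec, inverse = TRUE))
  fs_use <- n_use / duration
  if (n_use != n) {
    t_out <- (seq_len(n) - 1) / fs
    t_in <- (seq_len(n_use) - 1) / fs_use
    src <- approx(t_in, src, xout = pmin(t_out, t_in[n_use]))$y
  }
  s <- sd(src)
  if (s > 0) src / s else src
}

next_fast_len <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m + 1
  }
}

#' Generate a pair of band-coupled signals
#'
#' Two signals sharing a band-limited latent Gaussian source with
#' independent white channel noise, at possibly different sampling rates.
#' `snr` is the in-band power ratio of the shared source to the noise on
#' each channel, so the expected in-band magnitude coherence is
#' `1 / (1 + 1/snr)^2`; out-of-band coherence sits at the estimator's noise
#' floor.
#'
#' @param snr Non-negative source-to-noise variance ratio (may be `Inf` for
#'   noise-free copies).
#' @param band `c(lo, hi)` in Hz; `hi` must be below both Nyquist rates.
#' @param duration Length in seconds.
#' @param fs_x,fs_y Sampling rates of the two channels (Hz).
#' @param rng_seed Integer seed; calls are bit-reproducible.
#' @return List with [uniform_series] elements `x` and `y`.
#' @export
generate_coupled_pair <- function(snr, band, duration = 20,
                                  fs_x = 250, fs_y = 250, rng_seed = 1) {
  if (!is.numeric(snr) || snr < 0) stop("snr must be non-negative")
  if (band[2] >= min(fs_x, fs_y) / 2) {
    stop("invalid band: upper edge at or above Nyquist")
  }
  if (duration <= 0) stop("duration must be positive")
  nx <- round(duration * fs_x)
  ny <- round(duration * fs_y)
  with_seed(rng_seed, {
    co <- bl_source_coeffs(band, duration)
    sx <- bl_source_render(co, fs_x, nx)
    sy <- bl_source_render(co, fs_y, ny)
    wb <- band[2] - band[1]
    ax <- sqrt(snr * wb / (fs_x / 2))
    ay <- sqrt(snr * wb / (fs_y / 2))
    if (is.infinite(snr)) {
      x <- sx
      y <- sy
    } else {
      x <- ax * sx + rnorm(nx)
      y <- ay * sy + rnorm(ny)
    }
    list(x = uniform_series(x, fs_x), y = uniform_series(y, fs_y))
  })
}

# Ornstein-Uhlenbeck (AR(1)) sway process with stationary sd `scale`.
ou_trace <- function(n, fs, tau, scale) {
  if (scale <= 0) return(numeric(n))
  phi <- exp(-1 / (fs * tau))
  e <- rnorm(n, sd = scale * sqrt(1 - phi^2))
  e[1] <- rnorm(1, sd = scale)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' Generate a synthetic centre-of-pressure trace pair
#'
#' AP/ML sway as low-pass-shaped (AR(1)) noise with stationary amplitude
#' set by the ground truth's sway scales; stroke subjects sway more, with
#' an extra medio-lateral increase under high difficulty.
#'
#' @param difficulty `"low"`, `"medium"` or `"high"`.
#' @param group `"stroke"` or `"healthy"`.
#' @param duration Seconds (default 20).
#' @param fs Sampling rate (default 100 Hz).
#' @param rng_seed Integer seed.
#' @param truth A [ground_truth()] object.
#' @param subject_mult Per-subject sway multiplier (default 1).
#' @return List with numeric vectors `ap` and `ml` (cm) plus `fs`.
#' @export
generate_cop_trace <- function(difficulty, group, duration = 20, fs = 100,
                               rng_seed = 1, truth = ground_truth(),
                               subject_mult = 1) {
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  row <- truth$sway_scale[truth$sway_scale$difficulty == difficulty, ]
  s_ap <- row$ap * subject_mult
  s_ml <- row$ml * subject_mult *
    if (group == "stroke" && difficulty == "high") truth$sway_stroke_ml_high
    else 1
  n <- round(duration * fs)
  with_seed(rng_seed, {
    ap <- ou_trace(n, fs, truth$cop_tau, s_ap) +
      if (s_ap > 0) rnorm(1, sd = truth$cop_offset_sd) else 0
    ml <- ou_trace(n, fs, truth$cop_tau, s_ml) +
      if (s_ml > 0) rnorm(1, sd = truth$cop_offset_sd) else 0
    list(ap = ap, ml = ml, fs = fs)
  })
}

# Ground-truth feature values for one subject given its multipliers.
subject_truth_features <- function(truth, group, m_subj, chan, sway_m) {
  k <- function(muscle, side, difficulty) {
    coupling_snr(truth, muscle, side, truth$active_bands[[muscle]],
                 difficulty, group) * m_subj * chan[muscle, side]
  }
  ai <- function(muscle, difficulty) {
    a <- k(muscle, "AD", difficulty)
    l <- k(muscle, "LN", difficulty)
    if (a + l == 0) return(NA_real_)
    (a - l) / (a + l)
  }
  tmi <- function(muscle, side, hi, lo) {
    a <- k(muscle, side, hi)
    b <- k(muscle, side, lo)
    if (a + b == 0) return(NA_real_)
    (a - b) / (a + b)
  }
  sway <- function(direction, difficulty) {
    row <- truth$sway_scale[truth$sway_scale$difficulty == difficulty, ]
    base <- if (direction == "ml") row$ml else row$ap
    extra <- if (direction == "ml" && group == "stroke" &&
                 difficulty == "high") truth$sway_stroke_ml_high else 1
    base * sway_m * extra
  }
  c(
    AUC_TA_AD_delta_medcomb = k("TA", "AD", "medium"),
    AI_SOL_theta_medcomb = ai("SOL", "medium"),
    COP_ML_rms_highcomb = sway("ml", "high"),
    AI_BF_beta_highcomb = ai("BF", "high"),
    TMI_RF_LN_beta_HM = tmi("RF", "LN", "high", "medium")
  )
}

outcome_scores <- function(truth, feats) {
  z <- function(name) {
    row <- truth$feature_scaling[truth$feature_scaling$feature == name, ]
    (feats[[name]] - row$center) / row$scale
  }
  lin <- function(spec) {
    spec$intercept +
      sum(vapply(names(spec$weights),
                 function(nm) spec$weights[[nm]] * z(nm), numeric(1))) +
      rnorm(1, sd = spec$noise_sd)
  }
  bbs <- min(max(round(56 * plogis(lin(truth$outcome$bbs))), 0), 56)
  tug <- min(max(exp(lin(truth$outcome$tug)), 7), 60)
  list(bbs = as.integer(bbs), tug = tug)
}

trunc_norm <- function(p) {
  repeat {
    v <- rnorm(1, p[["mean"]], p[["sd"]])
    if (v >= p[["lo"]] && v <= p[["hi"]]) return(v)
  }
}

# One 20-s trial: EEG at 250 Hz carrying all coupled sources, 10 EMG
# channels at the native rate, and COP traces at 100 Hz.
simulate_trial <- function(truth, group, gain, m_subj, chan, sway_m,
                           duration = 20) {
  difficulty <- difficulty_of_gain(gain)
  n_eeg <- round(duration * EEG_FS)
  n_emg <- round(duration * EMG_FS)
  defs <- band_definitions()
  eeg <- rnorm(n_eeg)
  emg <- list()
  for (muscle in MUSCLES) {
    band_name <- truth$active_bands[[muscle]]
    b <- c(defs$lo[defs$band == band_name], defs$hi[defs$band == band_name])
    wb <- b[2] - b[1]
    for (side in SIDES) {
      kappa <- coupling_snr(truth, muscle, side, band_name, difficulty,
                            group) * m_subj * chan[muscle, side]
      co <- bl_source_coeffs(b, duration)
      s_eeg <- bl_source_render(co, EEG_FS, n_eeg)
      s_emg <- bl_source_render(co, EMG_FS, n_emg)
      a_e <- sqrt(kappa * wb / (EEG_FS / 2))
      a_m <- sqrt(kappa * wb / (EMG_FS / 2))
      eeg <- eeg + a_e * s_eeg
      emg[[paste(muscle, side, sep = ".")]] <- a_m * s_emg + rnorm(n_emg)
    }
  }
  cop_seed <- floor(runif(1) * 2^31)
  cop <- generate_cop_trace(difficulty, group, duration, COP_FS,
                            rng_seed = cop_seed, truth = truth,
                            subject_mult = sway_m)
  structure(list(gain = gain, difficulty = difficulty,
                 eeg = eeg, emg = emg, cop_ap = cop$ap, cop_ml = cop$ml,
                 fs_eeg = EEG_FS, fs_emg = EMG_FS, fs_cop = COP_FS),
            class = "cmc_trial")
}

#' Simulate a full cohort
#'
#' Generates `n_stroke + n_healthy` subjects, each with demographic
#' metadata, outcome scores derived from the subject's ground-truth feature
#' values, and up to six 20-s balance trials at gains
#' `{0, 0.6, -0.4, 0, 1.0, -1.0}` (trials are dropped independently with
#' the per-group, per-difficulty fall probability).
#'
#' @param n_stroke,n_healthy Group sizes (default 18 and 15).
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed; defaults to `truth$seed`. Identical truth and
#'   seed give a byte-identical cohort.
#' @return A `cmc_cohort` tibble: one row per subject with columns
#'   `subject_id`, `group`, `age`, `side`, `bbs`, `tug`, and list-columns
#'   `truth_features` (named ground-truth feature vector) and `trials`.
#' @export
simulate_cohort <- function(n_stroke = 18, n_healthy = 15,
                            truth = ground_truth(), seed = truth$seed) {
  stopifnot(n_stroke >= 0, n_healthy >= 0)
  groups <- c(rep("stroke", n_stroke), rep("healthy", n_healthy))
  n <- length(groups)
  miss <- truth$missing_prob
  rows <- with_seed(seed, lapply(seq_len(n), function(i) {
    group <- groups[i]
    age <- trunc_norm(truth$age[[group]])
    side <- if (group == "stroke") sample(c("left", "right"), 1) else "right"
    m_subj <- rlnorm(1, 0, truth$subject_sd)
    chan <- matrix(rlnorm(10, 0, truth$channel_sd), nrow = 5,
                   dimnames = list(MUSCLES, SIDES))
    sway_m <- rlnorm(1, 0, truth$sway_subject_sd)
    feats <- subject_truth_features(truth, group, m_subj, chan, sway_m)
    scores <- outcome_scores(truth, feats)
    trials <- list()
    for (gain in TRIAL_GAINS) {
      difficulty <- difficulty_of_gain(gain)
      p <- miss$prob[miss$group == group & miss$difficulty == difficulty]
      if (runif(1) < p) next
      trials[[length(trials) + 1]] <-
        simulate_trial(truth, group, gain, m_subj, chan, sway_m)
    }
    tibble::tibble(
      subject_id = sprintf("S%02d", i), group = group, age = age,
      side = side, bbs = scores$bbs, tug = scores$tug,
      truth_features = list(feats), trials = list(trials)
    )
  }))
  out <- dplyr::bind_rows(rows)
  if (n == 0) {
    out <- tibble::tibble(subject_id = character(), group = character(),
                          age = numeric(), side = character(),
                          bbs = integer(), tug = numeric(),
                          truth_features = list(), trials = list())
  }
  attr(out, "ground_truth") <- truth
  class(out) <- c("cmc_cohort", class(out))
  out
}
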