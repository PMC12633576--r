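# Signal conditioning shared by the feature extractors: EMG band-pass +
# resampling to the EEG rate, centre-of-mass estimation from centre of
# pressure, and COP velocity.

EEG_FS <- 250
EMG_FS <- 10000 / 9  # Delsys native rate, 1111.11 Hz
COP_FS <- 100

# Zero-phase filtering with odd (mirror) extension at both ends, scipy-style,
# so slow filters do not leak start-up transients into the series.
zero_phase_filter <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- n - 1L
  pad <- min(pad, n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(filt, ext)
  y[(pad + 1):(pad + n)]
}

# Exact band-limited sample-rate conversion: FFT of the mirror-extended
# signal (continuous periodic extension, so no wrap-around leakage), keep
# the bins below the output Nyquist, resynthesise on the output grid. The
# brick-wall spectrum doubles as the anti-alias filter: no imaging.
fft_resample <- function(x, fs_in, fs_out) {
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  X <- fft(c(x, rev(x)))
  m <- 2 * n_out
  keep <- floor(m / 2)
  Y <- complex(length.out = m)
  Y[1:keep] <- X[1:keep]
  Y[(m - keep + 2):m] <- X[(2 * n - keep + 2):(2 * n)]
  Re(fft(Y, inverse = TRUE))[1:n_out] / (2 * n)
}

#' Condition a raw EMG channel
#'
#' Prepares a surface EMG channel for corticomuscular coherence analysis:
#' removes the linear trend, applies the acquisition-style 20-450 Hz
#' Butterworth band-pass (single-pass causal, second-order edges, as in
#' the hardware), then resamples to 250 Hz (the EEG rate) by exact
#' band-limited FFT resampling, which is anti-aliasing by construction.
#' Every step is linear, and magnitude coherence is invariant to linear
#' filtering of one channel, so conditioning controls noise and alignment
#' without biasing coupling estimates; the gentle causal high-pass leaves
#' a usable (strongly attenuated but numerically clean) low-frequency
#' residue, which is what makes sub-20 Hz corticomuscular coherence
#' estimable at all after band-pass acquisition.
#'
#' @param raw EMG samples: a [uniform_series] or numeric vector.
#' @param fs Native sampling rate in Hz (defaults to 1111.11 Hz); required
#'   when `raw` is a bare vector. Must be within 5% of 1111.11 Hz.
#' @param band Pass band in Hz, default `c(20, 450)`.
#' @return A [uniform_series] at 250 Hz with `round(n * 250 / fs)` samples.
#' @examples
#' x <- rnorm(2222)
#' out <- condition_emg(x, fs = 1111.11)
#' out$fs
#' @export
condition_emg <- function(raw, fs = EMG_FS, band = c(20, 450)) {
  s <- as_series(raw, fs)
  x <- s$values
  if (abs(s$fs - EMG_FS) / EMG_FS > 0.05) {
    stop("condition_emg expects a native EMG rate near 1111.11 Hz")
  }
  n <- length(x)
  if (n < 50) stop("EMG series too short to condition")
  t <- seq_len(n)
  x <- x - stats::lm.fit(cbind(1, t), x)$fitted.values
  bp <- signal::butter(2, band / (s$fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bp, x))
  uniform_series(fft_resample(x, s$fs, EEG_FS), EEG_FS, t0 = s$t0)
}

#' Estimate centre of mass from centre of pressure
#'
#' Low-pass filters a COP trace with a second-order Butterworth at 0.86 Hz,
#' applied forward-backward so the centre-of-mass estimate has zero phase
#' lag relative to the COP.
#'
#' @param cop COP samples: a [uniform_series] or numeric vector.
#' @param fs Sampling rate in Hz (>= 10), required for bare vectors.
#' @param fc Cut-off frequency in Hz (default 0.86).
#' @return A [uniform_series] with the same length and rate as the input.
#' @export
estimate_com <- function(cop, fs = NULL, fc = 0.86) {
  s <- as_series(cop, fs)
  if (s$fs < 10) stop("estimate_com requires fs >= 10 Hz")
  if (length(s$values) < 3 * s$fs) {
    stop("COP series shorter than the 3 s filter warm-up")
  }
  lp <- signal::butter(2, fc / (s$fs / 2), type = "low")
  y <- zero_phase_filter(lp, s$values, pad = min(length(s$values) - 1L,
                                                 round(3 * s$fs)))
  uniform_series(y, s$fs, t0 = s$t0)
}

#' COP velocity by first differences
#'
#' @param cop COP samples: a [uniform_series] or numeric vector.
#' @param fs Sampling rate in Hz, required for bare vectors.
#' @return A [uniform_series] of length `n - 1` holding the first
#'   difference multiplied by the sampling rate (units per second).
#' @export
cop_velocity <- function(cop, fs = NULL) {
  s <- as_series(cop, fs)
  if (length(s$values) < 2) stop("need at least two samples")
  uniform_series(diff(s$values) * s$fs, s$fs, t0 = s$t0 + 0.5 / s$fs)
}
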