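# Wavelet corticomuscular coherence: Morlet CWT, smoothed magnitude
# coherence with cone-of-influence masking, bin/band averaging, Fisher
# z-transform, and significance calibration (closed form and Monte Carlo).

#' Frequency band definitions
#'
#' The five analysis bands used throughout: delta 0.05-4 Hz, theta 4-8 Hz,
#' alpha 8-12 Hz, beta 12-30 Hz, gamma 30-50 Hz.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.05, 4, 8, 12, 30),
    hi = c(4, 8, 12, 30, 50)
  )
}

resolve_band <- function(band) {
  defs <- band_definitions()
  if (is.character(band)) {
    row <- defs[defs$band == band, ]
    if (nrow(row) != 1) stop("unknown band: ", band)
    return(row)
  }
  if (is.data.frame(band) && all(c("lo", "hi") %in% names(band))) {
    return(band[1, ])
  }
  if (is.numeric(band) && length(band) == 2) {
    lo <- band[1]
    hi <- band[2]
    return(tibble::tibble(band = "custom", lo = lo, hi = hi))
  }
  stop("`band` must be a band name, a (lo, hi) pair, or a definitions row")
}

#' Logarithmic scale grid for the Morlet CWT
#'
#' Frequencies spaced at `voices` per octave, descending from `f_max` until
#' `f_min` is covered, so every analysis band lies on the grid.
#'
#' @param f_min,f_max Grid limits in Hz.
#' @param voices Scales per octave (default 10).
#' @return Numeric vector of frequencies in Hz, descending.
#' @export
cmc_scales <- function(f_min = 0.05, f_max = 50, voices = 10) {
  n <- ceiling(voices * log2(f_max / f_min))
  f_max * 2^(-(0:n) / voices)
}

morlet_fourier_factor <- function(omega0 = 6) .cpp_fourier_factor(omega0)

#' Morlet continuous wavelet transform
#'
#' @param x Signal: [uniform_series] or numeric vector.
#' @param fs Sampling rate in Hz (bare vectors only).
#' @param freqs Analysis frequencies in Hz; defaults to [cmc_scales()].
#' @param omega0 Morlet centre frequency (default 6).
#' @return Complex matrix, one row per frequency, with attributes `freqs`
#'   and `fs`.
#' @export
cwt_morlet <- function(x, fs = NULL, freqs = cmc_scales(), omega0 = 6) {
  s <- as_series(x, fs)
  W <- .cpp_cwt_morlet(s$values, s$fs, freqs, omega0)
  attr(W, "freqs") <- freqs
  attr(W, "fs") <- s$fs
  W
}

# Per-time minimum reliable frequency (Hz): the Morlet e-folding time is
# sqrt(2) * scale, so a cell is inside the cone of influence only when its
# scale is at most edge_distance / sqrt(2).
coi_frequencies <- function(n, fs, omega0 = 6) {
  ff <- morlet_fourier_factor(omega0)
  d <- pmin(seq_len(n) - 1, n - seq_len(n)) / fs
  out <- sqrt(2) / (ff * pmax(d, .Machine$double.eps))
  out[d == 0] <- Inf
  out
}

#' Wavelet coherence between two equally sampled signals
#'
#' Computes magnitude coherence in time-frequency space from Morlet CWTs:
#' `|S(Wx conj(Wy))|^2 / (S(|Wx|^2) S(|Wy|^2))`, where `S` is
#' scale-proportional Gaussian smoothing in time (sd = one scale) followed
#' by a boxcar across 0.6 octaves of scales, both applied to the
#' scale-normalised spectra. Without smoothing the ratio is identically 1;
#' the smoothing operator is what gives the estimator statistical meaning.
#' Analysis is restricted to the first `window_s` seconds.
#'
#' @param x,y Signals: [uniform_series] or numeric vectors of equal length
#'   and rate (250 Hz in the standard pipeline).
#' @param fs Sampling rate in Hz, required for bare vectors.
#' @param window_s Analysis window in seconds (default 18).
#' @param freqs Scale grid in Hz (descending); default [cmc_scales()].
#' @param voices Scales per octave of `freqs` (sets the scale-smoothing
#'   span).
#' @param omega0 Morlet centre frequency.
#' @param smooth If `FALSE`, return the unsmoothed ratio (identically 1;
#'   sanity-check path).
#' @return A `cmc_coherence` object: list with `coherence` (scales x times,
#'   in \[0, 1\]), `freqs`, `coi` (per-time minimum valid frequency, Hz),
#'   `fs`, `omega0`, `voices`.
#' @export
wavelet_coherence <- function(x, y, fs = NULL, window_s = 18,
                              freqs = cmc_scales(), voices = 10,
                              omega0 = 6, smooth = TRUE) {
  sx <- as_series(x, fs)
  sy <- as_series(y, fs)
  if (sx$fs != sy$fs) stop("x and y must share a sampling rate")
  if (length(sx$values) != length(sy$values)) {
    stop("x and y must have equal length")
  }
  n <- min(length(sx$values), round(window_s * sx$fs))
  xv <- sx$values[seq_len(n)]
  yv <- sy$values[seq_len(n)]

  if (!smooth) {
    Wx <- .cpp_cwt_morlet(xv, sx$fs, freqs, omega0)
    Wy <- .cpp_cwt_morlet(yv, sx$fs, freqs, omega0)
    num <- Mod(Wx * Conj(Wy))^2
    den <- Mod(Wx)^2 * Mod(Wy)^2
    coh <- ifelse(den > 0, pmin(num / den, 1), NA_real_)
  } else {
    h <- max(1L, as.integer(round(0.3 * voices)))
    px <- .cpp_wtc_prepare(xv, sx$fs, freqs, omega0)
    py <- .cpp_wtc_prepare(yv, sx$fs, freqs, omega0)
    coh <- .cpp_wtc_pair(px, py, h, 1L)
  }

  structure(
    list(coherence = coh, freqs = freqs,
         coi = coi_frequencies(n, sx$fs, omega0),
         fs = sx$fs, omega0 = omega0, voices = voices),
    class = "cmc_coherence"
  )
}

#' @export
print.cmc_coherence <- function(x, ...) {
  cat(sprintf("<cmc_coherence: %d scales (%.3g-%.3g Hz) x %d samples @ %g Hz>\n",
              nrow(x$coherence), min(x$freqs), max(x$freqs),
              ncol(x$coherence), x$fs))
  invisible(x)
}

# Logical matrix of in-COI cells for a coherence result.
coi_mask <- function(result) {
  outer(result$freqs, result$coi, ">=")
}

#' Average coherence over non-overlapping time bins
#'
#' Splits the analysis window into `bin_s`-second non-overlapping segments
#' (9 bins for an 18 s window) and averages coherence per scale within each
#' bin, using only cells inside the cone of influence. The first and last
#' bins are edge-contaminated and dropped by default, leaving 7 usable bins.
#'
#' @param result A `cmc_coherence` object.
#' @param bin_s Bin length in seconds (default 2).
#' @param drop_edges Drop the first and last bins (default `TRUE`).
#' @return Matrix (scales x kept bins) of bin means; all-masked cells are
#'   `NA`. Attributes: `freqs`, `n_bins_total`, `bins_kept`.
#' @export
bin_average <- function(result, bin_s = 2, drop_edges = TRUE) {
  stopifnot(inherits(result, "cmc_coherence"))
  n <- ncol(result$coherence)
  bin_n <- round(bin_s * result$fs)
  if (n %% bin_n != 0) {
    stop("analysis window length is not divisible by the bin length")
  }
  nb <- n %/% bin_n
  bin_of <- rep(seq_len(nb), each = bin_n)
  mask <- coi_mask(result)
  vals <- result$coherence
  vals[!mask] <- 0
  ind <- outer(bin_of, seq_len(nb), "==") + 0          # n x nb
  sums <- vals %*% ind
  counts <- mask %*% ind
  out <- ifelse(counts > 0, sums / counts, NA_real_)
  kept <- if (drop_edges && nb > 2) 2:(nb - 1) else seq_len(nb)
  out <- out[, kept, drop = FALSE]
  attr(out, "freqs") <- result$freqs
  attr(out, "n_bins_total") <- nb
  attr(out, "bins_kept") <- kept
  out
}

#' Average binned coherence over a frequency band
#'
#' Unweighted mean of all in-band, in-COI (scale, bin) cells.
#'
#' @param binned Matrix from [bin_average()] (or any scales x bins matrix).
#' @param band Band name ("delta".."gamma"), a `(lo, hi)` pair in Hz, or a
#'   row of [band_definitions()].
#' @param freqs Scale frequencies (Hz); defaults to the matrix attribute.
#' @return A single coherence value in \[0, 1\] (`NA` if every in-band cell
#'   is masked).
#' @export
band_average <- function(binned, band, freqs = attr(binned, "freqs")) {
  if (is.null(freqs)) stop("`freqs` is required")
  b <- resolve_band(band)
  sel <- freqs >= b$lo & freqs <= b$hi
  if (!any(sel)) stop("no scale on the grid falls inside the band")
  cells <- binned[sel, , drop = FALSE]
  if (all(is.na(cells))) return(NA_real_)
  mean(cells, na.rm = TRUE)
}

#' Fisher z-transform of a coherence value
#'
#' Variance-stabilising arc hyperbolic tangent, with coherence clipped just
#' below 1 so that perfect coherence maps to a large finite value.
#'
#' @param c Coherence in \[0, 1\] (vectorised).
#' @return `atanh(pmin(c, 1 - 1e-10))`.
#' @export
fisher_z <- function(c) {
  bad <- !is.na(c) & (c < 0 | c > 1)
  if (any(bad)) stop("coherence must lie in [0, 1]")
  atanh(pmin(c, 1 - 1e-10))
}

#' Closed-form coherence significance threshold
#'
#' For coherence estimated from `L` independent segments, the null
#' (1 - alpha) quantile is `1 - alpha^(1/(L - 1))`. With the study's 6
#' trials times 7 usable 2-s bins, `L = 42` and the threshold is 0.07 at
#' alpha = 0.05.
#'
#' @param L Number of independent segments (>= 2).
#' @param alpha Significance level in (0, 1).
#' @return The threshold on the coherence scale.
#' @examples
#' significance_threshold(42)  # ~0.0705
#' @export
significance_threshold <- function(L, alpha = 0.05) {
  if (!is.numeric(L) || length(L) != 1 || L < 2) stop("L must be >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  1 - alpha^(1 / (L - 1))
}

#' Effective number of coherence segments for a subject
#'
#' The closed-form threshold uses the study-level `L = 6 trials x 7
#' usable bins = 42` regardless of missingness; this helper gives the
#' per-subject effective count when trials were lost.
#'
#' @param n_trials Number of available trials.
#' @param bins_per_trial Usable bins per trial (default 7).
#' @return `n_trials * bins_per_trial`.
#' @export
effective_segments <- function(n_trials, bins_per_trial = 7) {
  n_trials * bins_per_trial
}

#' Serialize / read a coherence result
#'
#' Writes the coherence matrix as a gzip-compressed CSV alongside a JSON
#' sidecar carrying the frequency grid, cone of influence, sampling rate
#' and wavelet parameters.
#'
#' @param result A `cmc_coherence` object.
#' @param path Base path; `<path>.csv.gz` and `<path>.json` are written.
#' @return `write_coherence()` returns `path` invisibly;
#'   `read_coherence()` returns the reconstructed `cmc_coherence`.
#' @export
write_coherence <- function(result, path) {
  stopifnot(inherits(result, "cmc_coherence"))
  readr::write_csv(tibble::as_tibble(result$coherence, .name_repair = "minimal"),
                   paste0(path, ".csv.gz"), col_names = FALSE)
  coi <- result$coi
  coi[!is.finite(coi)] <- -1  # JSON has no Inf; -1 marks edge samples
  jsonlite::write_json(
    list(freqs = result$freqs, coi = coi, fs = result$fs,
         omega0 = result$omega0, voices = result$voices),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coherence
#' @export
read_coherence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(readr::read_csv(paste0(path, ".csv.gz"),
                                 col_names = FALSE, show_col_types = FALSE,
                                 progress = FALSE))
  dimnames(m) <- NULL
  coi <- meta$coi
  coi[coi < 0] <- Inf
  structure(list(coherence = m, freqs = meta$freqs, coi = coi,
                 fs = meta$fs, omega0 = meta$omega0, voices = meta$voices),
            class = "cmc_coherence")
}

#' Segment-pooled coherence across trials
#'
#' The estimator that the closed-form threshold of
#' [significance_threshold()] actually calibrates: per scale, one wavelet
#' coefficient is taken at the centre of each usable 2-s bin of each trial
#' (bin centres are separated by at least one wavelet decorrelation length
#' for all bands above the delta floor), and cross- and auto-spectra are
#' pooled over those L segments:
#' `|sum Wx conj(Wy)|^2 / (sum |Wx|^2 sum |Wy|^2)`.
#' Under independence the pooled value follows Goodman's null law with L
#' segments, so it exceeds `significance_threshold(L, alpha)` with
#' probability alpha. Segments outside the cone of influence are skipped.
#'
#' @param x_trials,y_trials Lists of paired trial signals (numeric vectors
#'   or [uniform_series]) at a common rate.
#' @param fs Sampling rate in Hz.
#' @param freqs Scale grid (Hz).
#' @param window_s,bin_s,drop_edges Windowing as in [bin_average()].
#' @param omega0 Morlet centre frequency.
#' @return Tibble with `freq`, `coherence`, `n_segments`.
#' @export
pooled_band_coherence <- function(x_trials, y_trials, fs = 250,
                                  freqs = cmc_scales(), window_s = 18,
                                  bin_s = 2, drop_edges = TRUE, omega0 = 6) {
  stopifnot(length(x_trials) == length(y_trials), length(x_trials) >= 1)
  nf <- length(freqs)
  cross <- complex(nf)
  ax <- numeric(nf)
  ay <- numeric(nf)
  nseg <- integer(nf)
  for (i in seq_along(x_trials)) {
    sx <- as_series(x_trials[[i]], fs)
    sy <- as_series(y_trials[[i]], fs)
    n <- min(length(sx$values), round(window_s * fs))
    bin_n <- round(bin_s * fs)
    nb <- n %/% bin_n
    kept <- if (drop_edges && nb > 2) 2:(nb - 1) else seq_len(nb)
    centres <- round((kept - 0.5) * bin_n)
    Wx <- .cpp_cwt_morlet(sx$values[seq_len(n)], fs, freqs, omega0)
    Wy <- .cpp_cwt_morlet(sy$values[seq_len(n)], fs, freqs, omega0)
    coi <- coi_frequencies(n, fs, omega0)
    for (s in seq_len(nf)) {
      ok <- centres[freqs[s] >= coi[centres]]
      if (!length(ok)) next
      wx <- Wx[s, ok]
      wy <- Wy[s, ok]
      cross[s] <- cross[s] + sum(wx * Conj(wy))
      ax[s] <- ax[s] + sum(Mod(wx)^2)
      ay[s] <- ay[s] + sum(Mod(wy)^2)
      nseg[s] <- nseg[s] + length(ok)
    }
  }
  coh <- ifelse(ax * ay > 0, Mod(cross)^2 / (ax * ay), NA_real_)
  tibble::tibble(freq = freqs, coherence = pmin(coh, 1), n_segments = nseg)
}

#' Monte Carlo significance thresholds for wavelet coherence
#'
#' Estimates per-scale null thresholds from surrogate signal pairs
#' generated by lag-1 autoregressive models matched to the inputs'
#' autocorrelation. The default statistic is the segment-pooled coherence
#' of [pooled_band_coherence()] (whose thresholds approach the closed form
#' for matched L); `statistic = "bin_mean"` instead thresholds the mean of
#' the smoothed coherence over usable in-COI bins.
#'
#' @param x,y Observed signals used to fit the AR(1) surrogate models, or
#'   lists `list(phi = , sd = , n = )` giving the models directly.
#' @param fs Sampling rate in Hz.
#' @param n_iter Number of surrogate iterations (>= 50 recommended).
#' @param alpha Significance level; `alpha = 1` returns zero thresholds.
#' @param freqs Scale grid (Hz).
#' @param statistic `"pooled"` or `"bin_mean"`.
#' @param seed RNG seed for the surrogate draws.
#' @param ... Passed to [wavelet_coherence()] / [pooled_band_coherence()].
#' @return Tibble with `freq` and `threshold`.
#' @export
monte_carlo_significance <- function(x, y, fs = 250, n_iter = 1000,
                                     alpha = 0.05, freqs = cmc_scales(),
                                     statistic = c("pooled", "bin_mean"),
                                     seed = 1, ...) {
  statistic <- match.arg(statistic)
  ar1_of <- function(v) {
    if (is.list(v)) return(v)
    s <- as_series(v, fs)$values
    phi <- suppressWarnings(cor(s[-1], s[-length(s)]))
    if (!is.finite(phi)) phi <- 0
    phi <- max(min(phi, 0.99), -0.99)
    list(phi = phi, sd = sd(s) * sqrt(1 - phi^2), n = length(s))
  }
  mx <- ar1_of(x)
  my <- ar1_of(y)
  if (alpha >= 1) {
    return(tibble::tibble(freq = freqs, threshold = 0))
  }
  sim_ar1 <- function(m) {
    e <- rnorm(m$n + 100, sd = m$sd)
    as.numeric(stats::filter(e, m$phi, method = "recursive"))[-seq_len(100)]
  }
  draws <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      xs <- sim_ar1(mx)
      ys <- sim_ar1(my)
      if (statistic == "pooled") {
        pooled_band_coherence(list(xs), list(ys), fs = fs, freqs = freqs,
                              ...)$coherence
      } else {
        res <- wavelet_coherence(xs, ys, fs = fs, freqs = freqs, ...)
        rowMeans(bin_average(res), na.rm = TRUE)
      }
    }, numeric(length(freqs)))
  })
  draws <- matrix(draws, nrow = length(freqs))
  thr <- apply(draws, 1, quantile, probs = 1 - alpha, na.rm = TRUE,
               names = FALSE)
  tibble::tibble(freq = freqs, threshold = thr)
}
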