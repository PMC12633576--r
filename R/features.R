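# Composite coherence indices, COP sway statistics, sample entropy, and the
# 528-column feature table schema.

#' Asymmetry index
#'
#' Normalised difference of corticomuscular coherence between the affected
#' (stroke) / dominant (healthy) side and the less-affected / nondominant
#' side: `(a - b) / (a + b)`. 0 is perfect symmetry; +/-1 is complete
#' asymmetry. The signed value is kept (negative when the affected side is
#' the weaker one); take `abs()` for a magnitude-only reading.
#'
#' @param cmc_a,cmc_b Non-negative coherence (or Fisher-z) values for the
#'   two sides; vectorised.
#' @return Values in \[-1, 1\]; `NA` where both inputs are 0.
#' @examples
#' asymmetry_index(0.6, 0.2)  # 0.5
#' @export
asymmetry_index <- function(cmc_a, cmc_b) {
  if (any(cmc_a < 0 | cmc_b < 0, na.rm = TRUE)) {
    stop("coherence values must be non-negative")
  }
  tot <- cmc_a + cmc_b
  ifelse(is.na(tot) | tot == 0, NA_real_, (cmc_a - cmc_b) / tot)
}

#' Task modulation index
#'
#' Normalised coherence change between two task-difficulty levels:
#' `(hi - lo) / (hi + lo)`, in \[-1, 1\]. Positive values mean coherence
#' grows with difficulty. Computed for the high-medium and medium-low
#' contrasts in the pipeline.
#'
#' @param cmc_hi,cmc_lo Non-negative coherence values at the harder and
#'   easier level; vectorised.
#' @return Values in \[-1, 1\]; `NA` where both inputs are 0.
#' @export
task_modulation_index <- function(cmc_hi, cmc_lo) {
  asymmetry_index(cmc_hi, cmc_lo)
}

#' Band area under the coherence spectrum
#'
#' Trapezoidal integral of a (time-averaged) coherence spectrum over a
#' frequency band, in coherence x Hz. Uses the in-band grid points;
#' missing values are dropped.
#'
#' @param freqs Frequencies in Hz (any order).
#' @param coherence Coherence values matching `freqs`.
#' @param band Band name, `(lo, hi)` pair, or a [band_definitions()] row.
#' @return The integral; errors if fewer than 2 usable in-band samples.
#' @export
band_auc <- function(freqs, coherence, band) {
  b <- resolve_band(band)
  sel <- freqs >= b$lo & freqs <= b$hi & !is.na(coherence)
  f <- freqs[sel]
  c_ <- coherence[sel]
  if (length(f) < 2) stop("need at least two in-band coherence samples")
  o <- order(f)
  f <- f[o]
  c_ <- c_[o]
  sum(diff(f) * (head(c_, -1) + tail(c_, -1)) / 2)
}

#' Sample entropy
#'
#' `-log(A / B)`, where `B` counts pairs of length-`m` templates and `A`
#' pairs of length-`m + 1` templates whose Chebyshev distance is strictly
#' below `r`; self-matches are excluded, pairs are counted once, and both
#' template sets run over starting indices `1..n - m` (Richman-Moorman
#' convention). A constant series returns 0 by convention (every template
#' matches).
#'
#' @param x Numeric series (length >= 50).
#' @param m Template length (default 2).
#' @param r Tolerance; defaults to `0.2 * sd(x)`.
#' @return Non-negative entropy; `NA` when no length-`m` template pairs
#'   match.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n >= 2 && sd(x) == 0) return(0)
  if (n < 50) stop("sample_entropy requires at least 50 samples")
  counts <- .cpp_sampen_counts(x, as.integer(m), r)
  if (counts[["B"]] == 0 || counts[["A"]] == 0) return(NA_real_)
  -log(counts[["A"]] / counts[["B"]])
}

#' COP summary statistics for one direction
#'
#' Mean, standard deviation, RMS about the trial mean, mean absolute
#' velocity, and sample entropy of a COP displacement series.
#'
#' @param cop COP trace ([uniform_series] or numeric), length >= 100.
#' @param fs Sampling rate (bare vectors).
#' @param direction Label, `"AP"` or `"ML"` (carried through, not used in
#'   the arithmetic).
#' @return One-row tibble: `direction`, `mean`, `std`, `rms`, `velocity`,
#'   `entropy`.
#' @export
cop_summary <- function(cop, fs = NULL, direction = "AP") {
  s <- as_series(cop, fs)
  x <- s$values
  if (length(x) < 100) stop("cop_summary requires at least 100 samples")
  cen <- x - mean(x)
  tibble::tibble(
    direction = direction,
    mean = mean(x),
    std = sd(x),
    rms = sqrt(mean(cen^2)),
    velocity = mean(abs(diff(x) * s$fs)),
    entropy = sample_entropy(x)
  )
}

#' 95% confidence ellipse area of a COP trajectory
#'
#' `pi * chi2(0.95, df = 2) * sqrt(det(Sigma))` with `Sigma` the 2x2 sample
#' covariance of (AP, ML); the chi-square critical value is 5.991. Units:
#' cm^2 for cm inputs.
#'
#' @param cop_ap,cop_ml Equal-length coordinate vectors (length >= 3).
#' @return The area; 0 (with a warning) for a degenerate covariance.
#' @export
ellipse_area_95 <- function(cop_ap, cop_ml) {
  stopifnot(length(cop_ap) == length(cop_ml), length(cop_ap) >= 3)
  S <- stats::cov(cbind(cop_ap, cop_ml))
  d <- det(S)
  if (!is.finite(d) || d <= .Machine$double.eps * max(prod(diag(S)), 1)) {
    warning("degenerate (collinear) COP trajectory; ellipse area is 0")
    return(0)
  }
  pi * qchisq(0.95, df = 2) * sqrt(d)
}

#' Path-length features of a COP trajectory
#'
#' Resultant increment series `d_i = sqrt(dAP_i^2 + dML_i^2)`, summarised
#' as total path length and the mean, sd, RMS and sample entropy of the
#' increments.
#'
#' @param cop_ap,cop_ml Equal-length coordinate vectors (length >= 2).
#' @return One-row tibble: `total`, `mean`, `std`, `rms`, `entropy`
#'   (entropy `NA` when the increment series is non-constant but too short
#'   to estimate).
#' @export
path_length_features <- function(cop_ap, cop_ml) {
  stopifnot(length(cop_ap) == length(cop_ml), length(cop_ap) >= 2)
  d <- sqrt(diff(cop_ap)^2 + diff(cop_ml)^2)
  near_const <- length(d) < 2 || sd(d) <= 1e-10 * max(abs(d), 1)
  ent <- if (near_const) 0
         else if (length(d) >= 50) sample_entropy(d) else NA_real_
  tibble::tibble(total = sum(d), mean = mean(d),
                 std = if (length(d) > 1) sd(d) else 0,
                 rms = sqrt(mean(d^2)), entropy = ent)
}

#' Registry of the 528 feature-table columns
#'
#' Enumerates the full schema: 150 band CMC columns (3 conditions x 2 side
#' pairings x 5 muscles x 5 bands), 75 asymmetry indices, 100 task
#' modulation indices (2 contrasts x 2 sides x 5 muscles x 5 bands), 150
#' band AUCs, 15 + 15 COP summary columns (AP/ML), 15 path-length columns,
#' 3 ellipse areas, and the subject, group, age, BBS and TUG columns.
#'
#' @return Tibble with `name`, `family`, `muscle`, `side`, `band`,
#'   `condition`, `stat` (NA where not applicable); 528 rows.
#' @export
feature_registry <- function() {
  bands <- band_definitions()$band
  conds <- unname(CONDITIONS)
  g <- function(...) tidyr::expand_grid(...)
  cmc <- g(muscle = MUSCLES, side = SIDES, band = bands, condition = conds) |>
    dplyr::mutate(family = "CMC", stat = NA_character_,
                  name = paste("CMC", .data$muscle, .data$side, .data$band,
                               .data$condition, sep = "_"))
  ai <- g(muscle = MUSCLES, band = bands, condition = conds) |>
    dplyr::mutate(family = "AI", side = NA_character_, stat = NA_character_,
                  name = paste("AI", .data$muscle, .data$band,
                               .data$condition, sep = "_"))
  tmi <- g(muscle = MUSCLES, side = SIDES, band = bands,
           condition = c("HM", "ML")) |>
    dplyr::mutate(family = "TMI", stat = NA_character_,
                  name = paste("TMI", .data$muscle, .data$side, .data$band,
                               .data$condition, sep = "_"))
  auc <- g(muscle = MUSCLES, side = SIDES, band = bands, condition = conds) |>
    dplyr::mutate(family = "AUC", stat = NA_character_,
                  name = paste("AUC", .data$muscle, .data$side, .data$band,
                               .data$condition, sep = "_"))
  stats5 <- c("mean", "std", "rms", "velocity", "entropy")
  cop <- g(side = c("AP", "ML"), stat = stats5, condition = conds) |>
    dplyr::mutate(family = paste0("COP-", .data$side),
                  muscle = NA_character_, band = NA_character_,
                  name = paste("COP", .data$side, .data$stat,
                               .data$condition, sep = "_"))
  pl <- g(stat = c("total", "mean", "std", "rms", "entropy"),
          condition = conds) |>
    dplyr::mutate(family = "COP-PL", muscle = NA_character_,
                  side = NA_character_, band = NA_character_,
                  name = paste("COP_PL", .data$stat, .data$condition,
                               sep = "_"))
  ell <- tibble::tibble(condition = conds) |>
    dplyr::mutate(family = "EllipseArea", muscle = NA_character_,
                  side = NA_character_, band = NA_character_,
                  stat = NA_character_,
                  name = paste("Ellipse_area", .data$condition, sep = "_"))
  meta <- tibble::tibble(
    name = c("subject", "group", "age", "bbs", "tug"),
    family = c("subject", "group", "age", "BBS", "TUG"),
    muscle = NA_character_, side = NA_character_, band = NA_character_,
    condition = NA_character_, stat = NA_character_
  )
  out <- dplyr::bind_rows(cmc, ai, tmi, auc, cop, pl, ell, meta) |>
    dplyr::select("name", "family", "muscle", "side", "band", "condition",
                  "stat")
  stopifnot(nrow(out) == 528, !anyDuplicated(out$name))
  out
}

# Condition label of a trial, as a column suffix.
condition_of <- function(difficulty) unname(CONDITIONS[difficulty])

# Per-trial coherence summaries for all 10 EEG-EMG pairs: band means over
# usable bins plus the time-averaged spectrum used for band AUC. Coherence
# is evaluated on a strided time grid (50 Hz effective), ample for 2-s bin
# means of fields smoothed over at least one wavelet scale.
trial_coherence <- function(trial, freqs = cmc_scales(), voices = 10,
                            window_s = 18, bin_s = 2, stride = 5L) {
  eeg <- trial$eeg
  n <- min(length(eeg), round(window_s * trial$fs_eeg))
  h <- max(1L, as.integer(round(0.3 * voices)))

  px <- .cpp_wtc_prepare(eeg[seq_len(n)], trial$fs_eeg, freqs, 6)
  tcols <- seq(1, n, by = stride)
  coi <- coi_frequencies(n, trial$fs_eeg, 6)[tcols]
  mask <- outer(freqs, coi, ">=")

  bin_n <- round(bin_s * trial$fs_eeg)
  nb <- n %/% bin_n
  kept <- 2:(nb - 1)
  bin_of <- pmin((tcols - 1) %/% bin_n + 1, nb)
  ind <- outer(bin_of, seq_len(nb), "==") + 0
  counts <- mask %*% ind

  defs <- band_definitions()
  band_sel <- lapply(seq_len(nrow(defs)), function(i) {
    freqs >= defs$lo[i] & freqs <= defs$hi[i]
  })
  names(band_sel) <- defs$band

  out_rows <- list()
  spectra <- list()
  for (ch in names(trial$emg)) {
    emg <- condition_emg(trial$emg[[ch]], fs = trial$fs_emg)
    py <- .cpp_wtc_prepare(emg$values[seq_len(n)], trial$fs_eeg, freqs, 6)
    coh <- .cpp_wtc_pair(px, py, h, stride)
    coh[!mask] <- 0
    binned <- (coh %*% ind) / ifelse(counts > 0, counts, NA_real_)
    usable <- binned[, kept, drop = FALSE]
    spec <- rowMeans(usable, na.rm = TRUE)
    spec[is.nan(spec)] <- NA_real_
    spectra[[ch]] <- spec
    parts <- strsplit(ch, ".", fixed = TRUE)[[1]]
    for (b in defs$band) {
      cells <- usable[band_sel[[b]], , drop = FALSE]
      out_rows[[length(out_rows) + 1]] <- tibble::tibble(
        muscle = parts[1], side = parts[2], band = b,
        coherence = if (all(is.na(cells))) NA_real_
                    else mean(cells, na.rm = TRUE)
      )
    }
  }
  list(bands = dplyr::bind_rows(out_rows),
       spectra = spectra, freqs = freqs)
}

# COP summaries for one trial.
trial_cop_features <- function(trial) {
  ap <- cop_summary(trial$cop_ap, fs = trial$fs_cop, direction = "AP")
  ml <- cop_summary(trial$cop_ml, fs = trial$fs_cop, direction = "ML")
  pl <- path_length_features(trial$cop_ap, trial$cop_ml)
  area <- suppressWarnings(ellipse_area_95(trial$cop_ap, trial$cop_ml))
  list(ap = ap, ml = ml, pl = pl, area = area)
}

#' Assemble the 528-column feature table for a cohort
#'
#' Runs the full per-trial signal pipeline (EMG conditioning, wavelet
#' coherence with COI masking, 2-s bin averaging with edge-bin exclusion)
#' and aggregates to per-condition features: Fisher-z band CMC, asymmetry
#' and task-modulation indices, band AUC by trapezoidal integration of the
#' condition-average coherence spectrum, COP summary/path-length/ellipse
#' features, plus subject metadata and outcomes. Conditions with no
#' surviving trial yield `NA` features (imputed later).
#'
#' @param cohort A `cmc_cohort` from [simulate_cohort()] (or an equivalent
#'   structure read back from disk).
#' @param freqs Wavelet scale grid; default [cmc_scales()].
#' @param voices Scales per octave of `freqs`.
#' @param progress Print one line per subject.
#' @return A tibble with 528 columns named per [feature_registry()], one
#'   row per subject, with attribute `registry`.
#' @export
extract_features <- function(cohort, freqs = cmc_scales(), voices = 10,
                             progress = FALSE) {
  reg <- feature_registry()
  defs <- band_definitions()
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    trials <- subj$trials[[1]]
    if (progress) {
      message(sprintf("features: %s (%d trials)", subj$subject_id,
                      length(trials)))
    }
    per_trial <- lapply(trials, function(tr) {
      c(list(condition = condition_of(tr$difficulty)),
        trial_coherence(tr, freqs = freqs, voices = voices),
        trial_cop_features(tr))
    })
    feat <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)

    for (cond in unname(CONDITIONS)) {
      sel <- vapply(per_trial, function(p) p$condition == cond, logical(1))
      if (!any(sel)) next
      pt <- per_trial[sel]
      # condition-average band coherence per (muscle, side, band)
      bands <- dplyr::bind_rows(lapply(pt, `[[`, "bands")) |>
        dplyr::summarise(coherence = mean(.data$coherence, na.rm = TRUE),
                         .by = c("muscle", "side", "band"))
      bands$coherence[is.nan(bands$coherence)] <- NA_real_
      for (j in seq_len(nrow(bands))) {
        nm <- paste("CMC", bands$muscle[j], bands$side[j], bands$band[j],
                    cond, sep = "_")
        feat[nm] <- fisher_z(bands$coherence[j])
      }
      # condition-average spectra -> band AUC
      for (ch in names(pt[[1]]$spectra)) {
        spec <- rowMeans(do.call(cbind, lapply(pt, function(p)
          p$spectra[[ch]])), na.rm = TRUE)
        spec[is.nan(spec)] <- NA_real_
        parts <- strsplit(ch, ".", fixed = TRUE)[[1]]
        for (b in defs$band) {
          nm <- paste("AUC", parts[1], parts[2], b, cond, sep = "_")
          feat[nm] <- tryCatch(band_auc(freqs, spec, b),
                               error = function(e) NA_real_)
        }
      }
      # COP families: per-trial statistics averaged within condition
      for (dir in c("AP", "ML")) {
        key <- tolower(dir)
        mat <- dplyr::bind_rows(lapply(pt, `[[`, key))
        for (st in c("mean", "std", "rms", "velocity", "entropy")) {
          feat[paste("COP", dir, st, cond, sep = "_")] <-
            mean(mat[[st]], na.rm = TRUE)
        }
      }
      plm <- dplyr::bind_rows(lapply(pt, `[[`, "pl"))
      for (st in c("total", "mean", "std", "rms", "entropy")) {
        feat[paste("COP_PL", st, cond, sep = "_")] <-
          mean(plm[[st]], na.rm = TRUE)
      }
      feat[paste("Ellipse_area", cond, sep = "_")] <-
        mean(vapply(pt, `[[`, numeric(1), "area"), na.rm = TRUE)
    }

    # composite indices from the condition band CMC (Fisher-z scale)
    zval <- function(muscle, side, band, cond) {
      feat[[paste("CMC", muscle, side, band, cond, sep = "_")]]
    }
    for (m in MUSCLES) for (b in defs$band) {
      for (cond in unname(CONDITIONS)) {
        a <- zval(m, "AD", b, cond)
        l <- zval(m, "LN", b, cond)
        feat[paste("AI", m, b, cond, sep = "_")] <-
          if (is.na(a) || is.na(l)) NA_real_ else asymmetry_index(a, l)
      }
      for (s in SIDES) {
        hi <- zval(m, s, b, "highcomb")
        md <- zval(m, s, b, "medcomb")
        lo <- zval(m, s, b, "lowcomb")
        feat[paste("TMI", m, s, b, "HM", sep = "_")] <-
          if (is.na(hi) || is.na(md)) NA_real_
          else task_modulation_index(hi, md)
        feat[paste("TMI", m, s, b, "ML", sep = "_")] <-
          if (is.na(md) || is.na(lo)) NA_real_
          else task_modulation_index(md, lo)
      }
    }
    feat["age"] <- subj$age
    feat["bbs"] <- subj$bbs
    feat["tug"] <- subj$tug
    feat["group"] <- if (subj$group == "stroke") 0 else 1
    out <- tibble::as_tibble(as.list(feat))
    out$subject <- subj$subject_id
    out
  })
  tbl <- dplyr::bind_rows(rows)[, reg$name]
  attr(tbl, "registry") <- reg
  class(tbl) <- c("cmc_features", class(tbl))
  tbl
}
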