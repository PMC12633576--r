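# On-disk cohort layout: one metadata CSV plus per-trial signal CSVs with a
# comment header line carrying the sampling rate.

write_signal_csv <- function(path, fs, df) {
  writeLines(sprintf("# fs=%.10g", fs), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

read_signal_csv <- function(path) {
  first <- readLines(path, n = 1)
  fs <- as.numeric(sub("# fs=", "", first, fixed = TRUE))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  list(fs = fs, data = df)
}

#' Write a cohort to a directory
#'
#' Layout: `metadata.csv` (subject_id, group, age, side, bbs, tug),
#' `trials.csv` (one row per stored trial with gain/difficulty and file
#' names), and under `signals/` three CSVs per trial (EEG, EMG, COP), each
#' starting with a `# fs=<rate>` comment line before the column header.
#' Generator ground-truth feature values are not serialised.
#'
#' @param cohort A `cmc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- cohort[c("subject_id", "group", "age", "side", "bbs", "tug")]
  readr::write_csv(tibble::as_tibble(meta), file.path(dir, "metadata.csv"))
  idx <- list()
  for (i in seq_len(nrow(cohort))) {
    trials <- cohort$trials[[i]]
    sid <- cohort$subject_id[i]
    for (k in seq_along(trials)) {
      tr <- trials[[k]]
      stem <- sprintf("%s_t%d", sid, k)
      write_signal_csv(file.path(dir, "signals", paste0(stem, "_eeg.csv")),
                       tr$fs_eeg, tibble::tibble(eeg_cz = tr$eeg))
      write_signal_csv(file.path(dir, "signals", paste0(stem, "_emg.csv")),
                       tr$fs_emg, tibble::as_tibble(tr$emg))
      write_signal_csv(file.path(dir, "signals", paste0(stem, "_cop.csv")),
                       tr$fs_cop,
                       tibble::tibble(ap = tr$cop_ap, ml = tr$cop_ml))
      idx[[length(idx) + 1]] <- tibble::tibble(
        subject_id = sid, trial = k, gain = tr$gain,
        difficulty = tr$difficulty, stem = stem)
    }
  }
  readr::write_csv(dplyr::bind_rows(idx), file.path(dir, "trials.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `cmc_cohort` tibble (with empty `truth_features`).
#' @export
read_cohort <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE, progress = FALSE)
  idx <- readr::read_csv(file.path(dir, "trials.csv"),
                         show_col_types = FALSE, progress = FALSE)
  trials_by_subject <- lapply(meta$subject_id, function(sid) {
    rows <- idx[idx$subject_id == sid, ]
    lapply(seq_len(nrow(rows)), function(j) {
      stem <- rows$stem[j]
      eeg <- read_signal_csv(file.path(dir, "signals",
                                       paste0(stem, "_eeg.csv")))
      emg <- read_signal_csv(file.path(dir, "signals",
                                       paste0(stem, "_emg.csv")))
      cop <- read_signal_csv(file.path(dir, "signals",
                                       paste0(stem, "_cop.csv")))
      structure(list(gain = rows$gain[j], difficulty = rows$difficulty[j],
                     eeg = eeg$data$eeg_cz, emg = as.list(emg$data),
                     cop_ap = cop$data$ap, cop_ml = cop$data$ml,
                     fs_eeg = eeg$fs, fs_emg = emg$fs, fs_cop = cop$fs),
                class = "cmc_trial")
    })
  })
  out <- tibble::as_tibble(meta)
  out$truth_features <- rep(list(NULL), nrow(out))
  out$trials <- trials_by_subject
  class(out) <- c("cmc_cohort", class(out))
  out
}
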