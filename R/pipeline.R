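# End-to-end orchestration: simulate -> features -> impute -> classify ->
# regress, with a written report bundle and manifest.

#' Pipeline configuration
#'
#' Collects every setting of an end-to-end run. Defaults reproduce the
#' study design: 18 stroke + 15 healthy subjects, model seeds 42/100/123,
#' split seed 42, regression seed 42, neighbour grid 1/3/5/7/9.
#'
#' @param n_stroke,n_healthy Cohort sizes.
#' @param truth_seed Seed of the synthetic ground truth / cohort.
#' @param seeds Stage-1 model seeds.
#' @param split_seed Stratified-split seed.
#' @param regression_seed Stage-2 seed.
#' @param k_grid Imputation neighbour grid.
#' @param out_dir Optional output directory for the report bundle.
#' @return A `cmc_pipeline_config` list.
#' @export
pipeline_config <- function(n_stroke = 18, n_healthy = 15, truth_seed = 1,
                            seeds = c(42, 100, 123), split_seed = 42,
                            regression_seed = 42,
                            k_grid = c(1, 3, 5, 7, 9), out_dir = NULL) {
  cfg <- list(n_stroke = n_stroke, n_healthy = n_healthy,
              truth_seed = truth_seed, seeds = seeds,
              split_seed = split_seed, regression_seed = regression_seed,
              k_grid = k_grid, out_dir = out_dir)
  if (cfg$n_stroke < 0 || cfg$n_healthy < 0) stop("invalid cohort sizes")
  structure(cfg, class = "cmc_pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, extracts the 528-column feature table, imputes
#' missing cells, runs stage-1 classification/feature selection and
#' stage-2 regression, and (when `out_dir` is set) writes the report
#' bundle: feature table CSV with JSON schema sidecar, stage reports as
#' JSON + CSV, embedding coordinates, and a manifest with seeds and MD5
#' checksums of every artifact.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (overrides the config's).
#' @param progress Print stage timings.
#' @return Invisibly, a list with `cohort`, `features`, `imputation`,
#'   `stage1`, `stage2`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = config$out_dir,
                         progress = FALSE) {
  stopifnot(inherits(config, "cmc_pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (progress) message(sprintf(...))

  cohort <- run_stage("simulate", {
    simulate_cohort(config$n_stroke, config$n_healthy,
                    truth = ground_truth(config$truth_seed))
  })
  say("simulate: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))

  feats <- run_stage("features", extract_features(cohort))
  say("features: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))

  imp <- run_stage("impute", impute_features(feats, k_grid = config$k_grid))
  stage1 <- run_stage("classify", {
    classify_cohort(imp$data, seeds = config$seeds,
                    split_seed = config$split_seed)
  })
  say("classify: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))

  stage2 <- run_stage("regress", {
    regress_outcomes(imp$data, stage1$retained, stage1$split,
                     seed = config$regression_seed)
  })
  say("regress: %.1fs", as.numeric(Sys.time() - t0, units = "secs"))

  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- run_stage("report", {
      write_report_bundle(out_dir, config, feats, imp, stage1, stage2)
    })
  }
  invisible(list(cohort = cohort, features = feats, imputation = imp,
                 stage1 = stage1, stage2 = stage2, manifest = manifest))
}

write_report_bundle <- function(out_dir, config, feats, imp, stage1,
                                stage2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  put <- function(name) {
    paths[[name]] <<- file.path(out_dir, name)
    paths[[name]]
  }

  readr::write_csv(tibble::as_tibble(feats), put("features.csv"), na = "")
  jsonlite::write_json(
    list(registry = attr(feats, "registry"),
         missing = lapply(tibble::as_tibble(feats), function(col)
           which(is.na(col)))),
    put("features_schema.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(imp$deviation_report, put("imputation_report.csv"))

  jsonlite::write_json(
    list(summary = stage1$summary, top_models = stage1$top_models,
         metrics = tidy(stage1),
         confusion = lapply(stage1$runs$result, function(r) r$confusion),
         chosen_k = imp$chosen_k),
    put("stage1_report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(stage1$ranking, put("feature_ranking.csv"))
  readr::write_csv(tibble::tibble(feature = stage1$retained),
                   put("retained_features.csv"))
  if (!is.null(stage1$embedding)) {
    readr::write_csv(stage1$embedding, put("embedding.csv"))
  }

  put_plot <- function(name, plot, width, height) {
    f <- file.path(out_dir, name)
    ok <- tryCatch({
      suppressMessages(ggplot2::ggsave(f, plot, width = width,
                                       height = height, dpi = 120))
      file.exists(f)
    }, error = function(e) FALSE)
    if (ok) paths[[name]] <<- f
  }
  if (!is.null(stage1$embedding)) {
    put_plot("embedding.png", plot_embedding(stage1), 5, 4)
  }

  jsonlite::write_json(
    list(metrics = tidy(stage2), predictors = stage2$predictors),
    put("stage2_report.json"), auto_unbox = TRUE, digits = NA)
  put_plot("predictions.png", plot_predictions(stage2), 8, 6)
  readr::write_csv(stage2$correlations, put("correlations.csv"))
  readr::write_csv(
    purrr::imap_dfr(stage2$fits, function(f, key)
      dplyr::mutate(f$predictions, fit = key, .before = 1)),
    put("predictions.csv"))

  manifest <- list(
    package = "cmcmarkers",
    version = as.character(utils::packageVersion("cmcmarkers")),
    config = unclass(config),
    checksums = as.list(tools::md5sum(unlist(paths)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
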