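# Stage 2: regression of BBS and TUG on the retained predictors, with the
# full metric suite, Shapley rankings, and Bonferroni-corrected Spearman
# feature analysis.

regression_metrics <- function(y, pred, p) {
  n <- length(y)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  adj <- if (n - p - 1 > 0 && !is.na(r2)) {
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  } else NA_real_
  fstat <- fp <- NA_real_
  if (n - p - 1 > 0 && ss_res > 0) {
    fstat <- ((ss_tot - ss_res) / p) / (ss_res / (n - p - 1))
    fp <- pf(fstat, p, n - p - 1, lower.tail = FALSE)
  }
  tibble::tibble(r2 = r2, adj_r2 = adj,
                 rmse = sqrt(mean((y - pred)^2)),
                 mae = mean(abs(y - pred)),
                 f_statistic = fstat, f_p_value = fp, n = n)
}

fit_reg_one <- function(family, x, y, params, seed) {
  switch(family,
    enet = {
      # glmnet requires >= 2 columns; pad a zero dummy when only one
      # predictor was retained
      dummy <- ncol(x) < 2
      if (dummy) x <- cbind(x, .dummy = 0)
      fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = params$alpha,
                            lambda = params$lambda, standardize = FALSE)
      list(kind = "glmnet_reg", fit = fit, lambda = params$lambda,
           dummy = dummy)
    },
    gbt = {
      d <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = d, nrounds = params$nrounds, verbose = 0)
      list(kind = "xgb_reg", fit = fit)
    },
    stop("unknown regression family: ", family)
  )
}

predict_reg <- function(model, x) {
  switch(model$kind,
    glmnet_reg = {
      x <- as.matrix(x)
      if (isTRUE(model$dummy)) x <- cbind(x, .dummy = 0)
      as.numeric(predict(model$fit, x, s = model$lambda))
    },
    xgb_reg = as.numeric(predict(model$fit,
                                 xgboost::xgb.DMatrix(as.matrix(x))))
  )
}

default_reg_grids <- function() {
  list(
    gbt = list(max_depth = c(2, 3, 4), eta = c(0.05, 0.1, 0.2),
               nrounds = c(50, 100, 200)),
    enet = list(alpha = c(0.1, 0.5, 0.9), lambda = c(0.01, 0.1, 1, 10))
  )
}

#' Tune and fit one regression family for one target
#'
#' Grid search by 5-fold cross-validated RMSE on the training rows
#' (predictors standardised with training statistics), refit on the full
#' training set, and evaluation on train and test, including adjusted R^2
#' (`1 - (1 - R^2)(n - 1)/(n - p - 1)`, `NA` when `n - p - 1 <= 0`) and the
#' regression-ANOVA F statistic (reported for both splits; ill-behaved on
#' a 9-sample test set, which is flagged with a warning).
#'
#' @param family `"gbt"` or `"enet"`.
#' @param data Feature table containing predictors and the target column.
#' @param predictors Character vector of predictor column names (must not
#'   include `bbs`/`tug`).
#' @param target `"bbs"` or `"tug"`.
#' @param train_idx,test_idx Row indices of the stage-1 split.
#' @param seed Seed (default 42).
#' @param cv_folds CV folds (default 5).
#' @return A `cmc_regfit` object with metrics, group-wise metrics,
#'   residuals, predictions and Shapley attributions.
#' @export
fit_regressor <- function(family, data, predictors, target,
                          train_idx, test_idx, seed = 42, cv_folds = 5) {
  if (any(c("bbs", "tug") %in% predictors)) {
    stop("outcome columns must not be used as predictors")
  }
  x_all_raw <- as.matrix(data[predictors])
  y_all <- data[[target]]
  x_tr_raw <- x_all_raw[train_idx, , drop = FALSE]
  ctr <- colMeans(x_tr_raw)
  scl <- apply(x_tr_raw, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  std <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  x_all <- std(x_all_raw)
  x_tr <- x_all[train_idx, , drop = FALSE]
  x_te <- x_all[test_idx, , drop = FALSE]
  y_tr <- y_all[train_idx]
  y_te <- y_all[test_idx]

  grid <- expand.grid(default_reg_grids()[[family]],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  folds <- with_seed(seed, {
    f <- rep_len(seq_len(cv_folds), length(y_tr))
    sample(f)
  })
  cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    errs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      m <- fit_reg_one(family, x_tr[tr, , drop = FALSE], y_tr[tr], params,
                       seed)
      sqrt(mean((y_tr[!tr] - predict_reg(m, x_tr[!tr, , drop = FALSE]))^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best_params <- as.list(grid[which.min(cv_rmse), , drop = FALSE])

  model <- fit_reg_one(family, x_tr, y_tr, best_params, seed)
  pred_tr <- predict_reg(model, x_tr)
  pred_te <- predict_reg(model, x_te)
  pred_all <- predict_reg(model, x_all)
  p <- length(predictors)
  if (length(y_te) - p - 1 <= 0) {
    warning("test split smaller than predictor count; ",
            "adjusted R^2 and F are not defined on the test set")
  }
  metrics <- dplyr::bind_rows(
    dplyr::mutate(regression_metrics(y_tr, pred_tr, p), split = "train",
                  .before = 1),
    dplyr::mutate(regression_metrics(y_te, pred_te, p), split = "test",
                  .before = 1))

  grp <- data$group
  group_metrics <- dplyr::bind_rows(lapply(c(0, 1), function(g) {
    lapply(list(train = train_idx, test = test_idx), function(idx) {
      sel <- idx[grp[idx] == g]
      if (length(sel) < 2) return(NULL)
      tibble::tibble(group = g,
                     rmse = sqrt(mean((y_all[sel] - pred_all[sel])^2)),
                     mae = mean(abs(y_all[sel] - pred_all[sel])),
                     n = length(sel))
    }) |> dplyr::bind_rows(.id = "split")
  }))

  shap_tr <- reg_shap(model, x_tr, x_tr)
  shap_te <- reg_shap(model, x_te, x_tr)

  structure(list(
    family = family, target = target, seed = seed, best_params = best_params,
    metrics = metrics, group_metrics = group_metrics,
    predictors = predictors, model = model, center = ctr, scale = scl,
    predictions = tibble::tibble(
      row = seq_along(y_all), group = grp, observed = y_all,
      predicted = pred_all,
      split = ifelse(seq_along(y_all) %in% train_idx, "train", "test")),
    residuals = y_all - pred_all,
    shap = list(train = shap_tr, test = shap_te),
    x = list(train = x_tr, test = x_te, all = x_all),
    split = list(train = train_idx, test = test_idx)
  ), class = "cmc_regfit")
}

reg_shap <- function(model, x, x_train) {
  switch(model$kind,
    glmnet_reg = {
      beta <- as.numeric(coef(model$fit, s = model$lambda))[-1]
      if (isTRUE(model$dummy)) beta <- beta[-length(beta)]
      sweep(x, 2, colMeans(x_train)) *
        matrix(beta, nrow(x), ncol(x), byrow = TRUE)
    },
    xgb_reg = {
      contrib <- predict(model$fit, xgboost::xgb.DMatrix(as.matrix(x)),
                         predcontrib = TRUE)
      contrib[, setdiff(colnames(contrib), c("BIAS", "(Intercept)")), drop = FALSE]
    }
  )
}

#' @export
print.cmc_regfit <- function(x, ...) {
  te <- x$metrics[x$metrics$split == "test", ]
  cat(sprintf("<cmc_regfit %s -> %s: test RMSE %.3f, R2 %.3f>\n",
              x$family, toupper(x$target), te$rmse, te$r2))
  invisible(x)
}

#' @describeIn fit_regressor Train/test metric rows.
#' @param x A `cmc_regfit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cmc_regfit <- function(x, ...) {
  dplyr::mutate(x$metrics, family = x$family, target = x$target,
                .before = 1)
}

#' @describeIn fit_regressor One-row summary (test metrics).
#' @exportS3Method generics::glance
glance.cmc_regfit <- function(x, ...) {
  te <- x$metrics[x$metrics$split == "test", ]
  tibble::tibble(family = x$family, target = x$target, test_rmse = te$rmse,
                 test_r2 = te$r2, test_mae = te$mae)
}

#' Spearman correlations between predictors and predicted scores
#'
#' Spearman rank correlation of every predictor with the model's predicted
#' outcome (pooled over all subjects by default), with asymptotic
#' tie-corrected p-values and a Bonferroni adjustment over the number of
#' predictors; significance at adjusted p < 0.05.
#'
#' @param fit A `cmc_regfit`.
#' @param scope `"pooled"` (all subjects, default) or `"train"`.
#' @return Tibble `feature`, `rho`, `p_value`, `p_bonferroni`,
#'   `significant` (constant predictors give `NA` rho and no flag).
#' @export
feature_correlations <- function(fit, scope = c("pooled", "train")) {
  scope <- match.arg(scope)
  idx <- if (scope == "train") fit$split$train
         else seq_len(nrow(fit$predictions))
  pred <- fit$predictions$predicted[idx]
  xm <- fit$x$all[idx, , drop = FALSE]
  n_feat <- length(fit$predictors)
  rows <- lapply(fit$predictors, function(f) {
    v <- xm[, f]
    if (sd(v) == 0 || sd(pred) == 0) {
      return(tibble::tibble(feature = f, rho = NA_real_, p_value = NA_real_,
                            p_bonferroni = NA_real_, significant = NA))
    }
    ct <- suppressWarnings(cor.test(v, pred, method = "spearman",
                                    exact = FALSE))
    pb <- min(1, ct$p.value * n_feat)
    tibble::tibble(feature = f, rho = unname(ct$estimate),
                   p_value = ct$p.value, p_bonferroni = pb,
                   significant = pb < 0.05)
  })
  dplyr::bind_rows(rows)
}

#' Rank predictors by mean absolute Shapley attribution
#'
#' @param fit A `cmc_regfit`.
#' @param split `"train"` (default) or `"test"`.
#' @return List with `ranking` (tibble `feature`, `mean_abs_shap`,
#'   descending) and `beeswarm` (long tibble of per-sample attribution and
#'   standardised feature value, for beeswarm-style plots).
#' @export
shap_rank <- function(fit, split = c("train", "test")) {
  split <- match.arg(split)
  sh <- fit$shap[[split]]
  xm <- fit$x[[split]]
  ranking <- tibble::tibble(
    feature = fit$predictors,
    mean_abs_shap = unname(colMeans(abs(sh)))
  ) |> dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  beeswarm <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::as_tibble(sh), row = seq_len(nrow(sh))),
    -"row", names_to = "feature", values_to = "shap") |>
    dplyr::left_join(
      tidyr::pivot_longer(
        dplyr::bind_cols(tibble::as_tibble(xm), row = seq_len(nrow(xm))),
        -"row", names_to = "feature", values_to = "value"),
      by = c("row", "feature"))
  list(ranking = ranking, beeswarm = beeswarm)
}

#' Run the full stage-2 regression analysis
#'
#' Fits both regression families (gradient-boosted trees and elastic-net
#' linear) for both targets (BBS, TUG) on the retained predictors, using
#' the same stratified split as stage 1, and attaches Spearman feature
#' correlations and Shapley rankings per fit.
#'
#' @param features Imputed feature table.
#' @param retained Retained feature names from stage 1 (BBS/TUG and
#'   metadata columns are removed automatically to form the predictors).
#' @param split The stage-1 split (list with `train` and `test`).
#' @param targets Outcomes to model (default `c("bbs", "tug")`).
#' @param families Regression families (default `c("gbt", "enet")`).
#' @param seed Seed (default 42).
#' @return A `cmc_stage2` object: list of fits keyed `target_family`,
#'   `predictors`, plus `correlations` (tibble over all fits).
#' @export
regress_outcomes <- function(features, retained, split,
                             targets = c("bbs", "tug"),
                             families = c("gbt", "enet"), seed = 42) {
  predictors <- setdiff(retained, c("bbs", "tug", "subject", "group"))
  if (!length(predictors)) stop("no predictors retained")
  fits <- list()
  for (target in targets) {
    for (family in families) {
      fits[[paste(target, family, sep = "_")]] <-
        fit_regressor(family, features, predictors, target,
                      split$train, split$test, seed = seed)
    }
  }
  correlations <- purrr::imap_dfr(fits, function(f, key) {
    dplyr::mutate(feature_correlations(f), fit = key, target = f$target,
                  family = f$family, .before = 1)
  })
  structure(list(fits = fits, predictors = predictors,
                 correlations = correlations, seed = seed),
            class = "cmc_stage2")
}

#' @export
print.cmc_stage2 <- function(x, ...) {
  cat("<cmc_stage2>\n")
  cat("  predictors:", length(x$predictors), "\n")
  for (f in x$fits) print(f)
  invisible(x)
}

#' @describeIn regress_outcomes Metrics of every fit, long.
#' @param x A `cmc_stage2` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cmc_stage2 <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' @describeIn regress_outcomes One row per fit.
#' @exportS3Method generics::glance
glance.cmc_stage2 <- function(x, ...) {
  purrr::map_dfr(x$fits, glance)
}
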