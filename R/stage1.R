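# Stage 1: stroke-vs-healthy classification across seven model families and
# three seeds, Shapley consolidation, frequency-based feature retention, and
# a 2-D embedding of the retained feature space.

#' Stratified train/test split
#'
#' Splits rows into train and test preserving class proportions: the test
#' size is `ceiling(n * test_frac)`, allocated across classes by largest
#' remainder, so 33 subjects (18 stroke / 15 healthy) give 24 train and 9
#' test (5 stroke + 4 healthy in test).
#'
#' @param y Class labels (vector), or a data frame with a `group` column.
#' @param test_frac Test fraction (default 0.25).
#' @param seed RNG seed (default 42).
#' @return List with integer row indices `train` and `test`.
#' @export
stratified_split <- function(y, test_frac = 0.25, seed = 42) {
  if (is.data.frame(y)) y <- y$group
  classes <- split(seq_along(y), y)
  if (any(lengths(classes) < 2)) {
    stop("each class needs at least 2 members")
  }
  n <- length(y)
  n_test <- ceiling(n * test_frac)
  exact <- lengths(classes) * n_test / n
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  with_seed(seed, {
    test <- unlist(lapply(seq_along(classes), function(i) {
      idx <- classes[[i]]
      sample(idx, base[i])
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Default classification model specifications
#'
#' The seven families with their hyperparameter grids: elastic-net,
#' random forest, gradient-boosted trees, L1 and L2 logistic regression,
#' AdaBoost (decision stumps), and SVM (linear/RBF). The listed order is
#' the stable tie-break order used by [select_top_models()]: the sparse
#' interpretable selector first, then the dense bagged ensemble, so that
#' when several families tie at the ceiling (common on a 9-sample test
#' set with well-separated groups) the consolidation stage receives two
#' complementary attribution profiles — a sparse linear one and a dense
#' tree one — which is what the 4-of-6 retention rule is designed around.
#'
#' @return Named list of model specs (`family`, `label`, `grid`).
#' @export
default_model_specs <- function() {
  lam <- c(0.001, 0.01, 0.1, 1)
  list(
    enet = list(family = "enet", label = "Logistic Regression (Elastic Net)",
                grid = list(lambda = lam)),
    rf = list(family = "rf", label = "Random Forest",
              grid = list(n_estimators = c(50, 100, 200),
                          max_depth = c(2, 4, 6, 10))),
    gbt = list(family = "gbt", label = "Gradient Boosted Trees",
               grid = list(max_depth = c(2, 3, 4),
                           eta = c(0.01, 0.1, 0.2),
                           nrounds = c(50, 100, 200))),
    l1 = list(family = "l1", label = "Logistic Regression (L1)",
              grid = list(lambda = lam)),
    l2 = list(family = "l2", label = "Logistic Regression (L2)",
              grid = list(lambda = lam)),
    ada = list(family = "ada", label = "AdaBoost",
               grid = list(nrounds = c(50, 100, 200))),
    svm = list(family = "svm", label = "SVM",
               grid = list(cost = c(0.001, 0.01, 0.1, 1, 10),
                           kernel = c("linear", "radial")))
  )
}

# Fit one family at fixed hyperparameters on a standardised matrix.
fit_one <- function(family, x, y, params, seed) {
  switch(family,
    enet = , l1 = , l2 = {
      alpha <- c(enet = 0.5, l1 = 1, l2 = 0)[[family]]
      # glmnet warns about class counts on every small CV fold; expected
      # at n = 16, so silenced here
      fit <- withCallingHandlers(
        glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                       lambda = params$lambda, standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      list(kind = "glmnet", fit = fit, lambda = params$lambda)
    },
    gbt = {
      d <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      subsample = 0.8, colsample_bynode = 0.3,
                      nthread = 1, seed = seed),
        data = d, nrounds = params$nrounds, verbose = 0)
      list(kind = "xgb", fit = fit)
    },
    rf = {
      d <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 1,
                      max_depth = params$max_depth,
                      num_parallel_tree = params$n_estimators,
                      subsample = 0.632,
                      colsample_bynode = max(sqrt(ncol(x)) / ncol(x), 0.01),
                      nthread = 1, seed = seed),
        data = d, nrounds = 1, verbose = 0)
      list(kind = "xgb", fit = fit)
    },
    ada = {
      fit <- .cpp_ada_fit(x, ifelse(y == 1, 1, -1), params$nrounds)
      list(kind = "ada", fit = fit, nrounds = params$nrounds)
    },
    svm = {
      yf <- factor(y, levels = c(0, 1))
      fit <- e1071::svm(x, yf, kernel = params$kernel, cost = params$cost,
                        scale = FALSE)
      list(kind = "svm", fit = fit)
    },
    stop("unknown family: ", family)
  )
}

# Decision margin oriented so larger values favour class 1.
predict_margin <- function(model, x) {
  switch(model$kind,
    glmnet = as.numeric(predict(model$fit, x, s = model$lambda,
                                type = "link")),
    xgb = {
      d <- xgboost::xgb.DMatrix(as.matrix(x))
      as.numeric(predict(model$fit, d, outputmargin = TRUE))
    },
    ada = {
      m <- .cpp_ada_margin(as.matrix(x), model$fit$feature,
                           model$fit$threshold, model$fit$polarity,
                           model$fit$alpha,
                           as.integer(min(model$nrounds,
                                          length(model$fit$alpha))))
      as.numeric(m[, 1])
    },
    svm = {
      pr <- predict(model$fit, as.matrix(x), decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      # e1071 orients decision values towards the first factor level ("0")
      nm <- colnames(attr(pr, "decision.values"))
      if (length(nm) && startsWith(nm, "0")) dv <- -dv
      dv
    }
  )
}

# Stratified fold assignment (1..k) for binary labels.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

classification_metrics <- function(y, margin) {
  pred <- as.integer(margin > 0)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  cm <- table(factor(y, levels = c(0, 1)), factor(pred, levels = c(0, 1)),
              dnn = c("actual", "predicted"))
  list(metrics = tibble::tibble(
         accuracy = mean(pred == y), precision = precision, recall = recall,
         f1 = f1, roc_auc = auc_score(y, margin)),
       confusion = unclass(cm))
}

#' Tune and fit one classification family
#'
#' Grid search by stratified k-fold cross-validated ROC AUC on the training
#' rows (features standardised with training statistics only), refit on the
#' full training set, and evaluation on train and test.
#'
#' @param spec A model spec from [default_model_specs()].
#' @param train,test Tibbles of numeric features plus a `group` column
#'   (0 = stroke, 1 = healthy).
#' @param seed Seed controlling CV shuffling and model stochasticity.
#' @param cv_folds Number of CV folds (default 3).
#' @param compute_shap Also compute Shapley attributions for train and test.
#' @return A `cmc_run` object: family, seed, `best_params`, `metrics`
#'   (per-split tibble), `confusion`, `shap` (list or NULL), the fitted
#'   model, and the standardisation used.
#' @export
tune_and_fit <- function(spec, train, test, seed = 42, cv_folds = 3,
                         compute_shap = TRUE) {
  y_tr <- train$group
  y_te <- test$group
  feat_cols <- setdiff(names(train)[vapply(train, is.numeric, logical(1))],
                       "group")
  x_tr_raw <- as.matrix(train[feat_cols])
  x_te_raw <- as.matrix(test[feat_cols])
  ctr <- colMeans(x_tr_raw)
  scl <- apply(x_tr_raw, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  x_tr <- sweep(sweep(x_tr_raw, 2, ctr), 2, scl, "/")
  x_te <- sweep(sweep(x_te_raw, 2, ctr), 2, scl, "/")

  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  folds <- stratified_folds(y_tr, cv_folds, seed)
  cv_scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    scores <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (min(table(factor(y_tr[tr], levels = c(0, 1)))) < 2 ||
          length(unique(y_tr[!tr])) < 2) {
        stop("degenerate CV fold: a split lacks class representation")
      }
      m <- fit_one(spec$family, x_tr[tr, , drop = FALSE], y_tr[tr], params,
                   seed)
      margin <- predict_margin(m, x_tr[!tr, , drop = FALSE])
      # log-loss of the margin through a logistic link, as an AUC tie-break
      pp <- plogis(pmin(pmax(margin, -30), 30))
      ll <- -mean(y_tr[!tr] * log(pmax(pp, 1e-12)) +
                    (1 - y_tr[!tr]) * log(pmax(1 - pp, 1e-12)))
      c(auc_score(y_tr[!tr], margin), ll)
    }, numeric(2))
    rowMeans(scores)
  }, numeric(2))
  # best mean CV AUC; ties (common on small folds) broken by smaller mean
  # log-loss, then stable grid order
  best <- order(-cv_scores[1, ], cv_scores[2, ])[1]
  best_params <- as.list(grid[best, , drop = FALSE])

  model <- fit_one(spec$family, x_tr, y_tr, best_params, seed)
  m_tr <- predict_margin(model, x_tr)
  m_te <- predict_margin(model, x_te)
  res_tr <- classification_metrics(y_tr, m_tr)
  res_te <- classification_metrics(y_te, m_te)

  run <- structure(list(
    family = spec$family, label = spec$label, seed = seed,
    best_params = best_params, cv_auc = cv_scores[1, best],
    metrics = dplyr::bind_rows(
      dplyr::mutate(res_tr$metrics, split = "train", .before = 1),
      dplyr::mutate(res_te$metrics, split = "test", .before = 1)),
    confusion = list(train = res_tr$confusion, test = res_te$confusion),
    model = model, center = ctr, scale = scl, feat_cols = feat_cols,
    x_train = x_tr, x_test = x_te, shap = NULL
  ), class = "cmc_run")
  if (compute_shap) {
    run$shap <- list(train = shapley_attribution(run, x_tr),
                     test = shapley_attribution(run, x_te))
  }
  run
}

#' @export
print.cmc_run <- function(x, ...) {
  te <- x$metrics[x$metrics$split == "test", ]
  cat(sprintf("<cmc_run %s seed %d: test AUC %.3f, acc %.3f>\n",
              x$label, x$seed, te$roc_auc, te$accuracy))
  invisible(x)
}

#' Shapley attributions for a fitted run
#'
#' Exact attribution routes per family: TreeSHAP (`predcontrib`) for the
#' tree ensembles, closed-form `coef * (x - background)` for the penalised
#' logistic models, exact per-feature decomposition for the additive stump
#' ensemble, and sampling [kernel_shap()] for the SVM. Attributions plus
#' the base value reconstruct the model margin.
#'
#' @param run A `cmc_run` from [tune_and_fit()].
#' @param x Standardised feature matrix to attribute (defaults to the run's
#'   training matrix).
#' @param nsim Coalition samples for the kernel route.
#' @return Matrix (rows x features) of attributions.
#' @export
shapley_attribution <- function(run, x = run$x_train, nsim = 1024) {
  x <- as.matrix(x)
  model <- run$model
  bg <- colMeans(run$x_train)
  switch(model$kind,
    glmnet = {
      beta <- as.numeric(coef(model$fit, s = model$lambda))[-1]
      sweep(x, 2, bg) * matrix(beta, nrow(x), ncol(x), byrow = TRUE)
    },
    xgb = {
      d <- xgboost::xgb.DMatrix(x)
      contrib <- predict(model$fit, d, predcontrib = TRUE)
      contrib[, setdiff(colnames(contrib), c("BIAS", "(Intercept)")), drop = FALSE]
    },
    ada = {
      fit <- model$fit
      n_use <- min(model$nrounds, length(fit$alpha))
      phi <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
      for (m in seq_len(n_use)) {
        j <- fit$feature[m] + 1L
        h_x <- ifelse(x[, j] > fit$threshold[m], fit$polarity[m],
                      -fit$polarity[m])
        h_bg <- mean(ifelse(run$x_train[, j] > fit$threshold[m],
                            fit$polarity[m], -fit$polarity[m]))
        phi[, j] <- phi[, j] + fit$alpha[m] * (h_x - h_bg)
      }
      phi
    },
    svm = {
      f <- function(m) {
        colnames(m) <- colnames(run$x_train)
        predict_margin(model, m)
      }
      kernel_shap(f, x, bg, nsim = nsim, seed = run$seed)
    }
  )
}

#' Select the top two model families
#'
#' Ranks families by mean test ROC AUC (descending), breaking ties by the
#' smaller standard deviation across seeds and then by the stable
#' registration order of [default_model_specs()].
#'
#' @param summary Tibble with `family`, `mean_auc`, `sd_auc` and an
#'   implicit row order giving the stable tie-break.
#' @return Character vector of the top (up to) two family ids.
#' @export
select_top_models <- function(summary) {
  o <- order(-summary$mean_auc, summary$sd_auc, seq_len(nrow(summary)))
  top <- summary$family[o]
  if (length(top) < 2) {
    warning("fewer than two families available; returning all")
    return(top)
  }
  top[1:2]
}

#' Consolidate Shapley attributions into a feature ranking
#'
#' Counts, per feature, in how many of the six runs (top-2 families x 3
#' seeds) the mean absolute attribution over train + test samples is
#' non-zero (> 1e-10); features present in at least 4 of 6 runs are
#' retained.
#'
#' @param runs List of exactly 6 `cmc_run` objects with attributions.
#' @param min_count Retention threshold (default 4).
#' @return Tibble `feature`, per-family frequency columns, `total`,
#'   `retained`, sorted by total descending.
#' @export
consolidate_features <- function(runs, min_count = 4) {
  if (length(runs) != 6) stop("expected exactly 6 runs (2 families x 3 seeds)")
  feats <- runs[[1]]$feat_cols
  fams <- vapply(runs, `[[`, character(1), "family")
  nz <- vapply(runs, function(r) {
    sh <- rbind(r$shap$train, r$shap$test)
    colMeans(abs(sh)) > 1e-10
  }, logical(length(feats)))
  rownames(nz) <- feats
  out <- tibble::tibble(feature = feats)
  for (fam in unique(fams)) {
    out[[paste0("freq_", fam)]] <-
      unname(rowSums(nz[, fams == fam, drop = FALSE]))
  }
  out$total <- unname(rowSums(nz))
  out$retained <- out$total >= min_count
  dplyr::arrange(out, dplyr::desc(.data$total), .data$feature)
}

#' Two-dimensional embedding of the retained feature space
#'
#' Classical multidimensional scaling (principal coordinates) of the
#' Euclidean distances between standardised retained-feature rows, used
#' only for visualising group separation. Deterministic for a given input;
#' the `seed` argument is accepted for interface stability.
#'
#' @param x Numeric data frame / matrix (samples x features), >= 4 rows.
#' @param seed Unused (embedding is deterministic).
#' @return Tibble with `dim1`, `dim2`.
#' @export
embed_2d <- function(x, seed = 42) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("embedding needs at least 4 samples")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  k <- min(2, nrow(x) - 1)
  co <- stats::cmdscale(stats::dist(z), k = k)
  if (ncol(co) < 2) co <- cbind(co, 0)
  tibble::tibble(dim1 = co[, 1], dim2 = co[, 2])
}

#' Run the full stage-1 classification
#'
#' Stratified 75/25 split (fixed split seed), all seven families tuned and
#' fitted across the model seeds, top-2 selection by mean test ROC AUC,
#' Shapley consolidation over the 6 top-family runs, retention at >= 4/6,
#' and a 2-D embedding of the retained features.
#'
#' @param features Imputed feature table (from [impute_features()]`$data`
#'   or [extract_features()] when complete).
#' @param seeds Model seeds (default 42, 100, 123).
#' @param specs Model specifications (default [default_model_specs()]).
#' @param split_seed Seed of the stratified split (default 42).
#' @param test_frac Test fraction (default 0.25).
#' @param cv_folds CV folds for tuning (default 3).
#' @return A `cmc_stage1` object: `runs` (tibble with list-column
#'   `result`), `summary`, `top_models`, `ranking`, `retained`, `split`,
#'   `embedding`.
#' @export
classify_cohort <- function(features, seeds = c(42, 100, 123),
                            specs = default_model_specs(), split_seed = 42,
                            test_frac = 0.25, cv_folds = 3) {
  drop_cols <- intersect(c("subject"), names(features))
  tbl <- features[setdiff(names(features), drop_cols)]
  split <- stratified_split(tbl$group, test_frac = test_frac,
                            seed = split_seed)
  train <- tbl[split$train, ]
  test <- tbl[split$test, ]

  runs <- list()
  for (spec in specs) {
    for (seed in seeds) {
      key <- paste(spec$family, seed, sep = "_")
      runs[[key]] <- tune_and_fit(spec, train, test, seed = seed,
                                  cv_folds = cv_folds, compute_shap = FALSE)
    }
  }
  run_tbl <- tibble::tibble(
    family = vapply(runs, `[[`, character(1), "family"),
    label = vapply(runs, `[[`, character(1), "label"),
    seed = vapply(runs, `[[`, numeric(1), "seed"),
    test_auc = vapply(runs, function(r) {
      r$metrics$roc_auc[r$metrics$split == "test"]
    }, numeric(1)),
    result = unname(runs)
  )
  fam_order <- vapply(specs, `[[`, character(1), "family")
  summary <- run_tbl |>
    dplyr::summarise(mean_auc = mean(.data$test_auc),
                     sd_auc = sd(.data$test_auc), .by = "family") |>
    dplyr::arrange(match(.data$family, fam_order))
  top <- select_top_models(summary)

  top_runs <- runs[run_tbl$family %in% top]
  for (key in names(top_runs)) {
    r <- top_runs[[key]]
    r$shap <- list(train = shapley_attribution(r, r$x_train),
                   test = shapley_attribution(r, r$x_test))
    top_runs[[key]] <- r
    runs[[key]] <- r
  }
  ranking <- consolidate_features(unname(top_runs))
  retained <- ranking$feature[ranking$retained]

  emb_cols <- intersect(retained, names(tbl))
  embedding <- if (length(emb_cols) >= 1 && nrow(tbl) >= 4) {
    dplyr::bind_cols(
      embed_2d(tbl[emb_cols], seed = split_seed),
      tibble::tibble(group = tbl$group)
    )
  } else NULL

  run_tbl$result <- unname(runs)
  structure(list(runs = run_tbl, summary = summary, top_models = top,
                 ranking = ranking, retained = retained, split = split,
                 embedding = embedding,
                 feature_names = runs[[1]]$feat_cols),
            class = "cmc_stage1")
}

#' @export
print.cmc_stage1 <- function(x, ...) {
  cat("<cmc_stage1>\n")
  cat("  top models:", paste(x$top_models, collapse = ", "), "\n")
  cat("  retained features:", length(x$retained), "\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn classify_cohort Per-run metrics as a long tibble.
#' @param x A `cmc_stage1` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cmc_stage1 <- function(x, ...) {
  purrr::map_dfr(x$runs$result, function(r) {
    dplyr::mutate(r$metrics, family = r$family, label = r$label,
                  seed = r$seed, .before = 1)
  })
}

#' @describeIn classify_cohort Per-family summary (mean/sd test ROC AUC).
#' @exportS3Method generics::glance
glance.cmc_stage1 <- function(x, ...) x$summary
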