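test_that("stratified split reproduces the 24/9 arithmetic", {
  y33 <- rep(c(0, 1), c(18, 15))
  sp <- stratified_split(y33, 0.25, seed = 42)
  expect_length(sp$train, 24)
  expect_length(sp$test, 9)
  expect_equal(sum(y33[sp$test] == 0), 5)   # 18 * 9/33 = 4.9 -> 5
  expect_equal(sum(y33[sp$test] == 1), 4)
  expect_equal(sort(c(sp$train, sp$test)), 1:33)

  # balanced 4-sample case at 50%
  sp4 <- stratified_split(c(0, 0, 1, 1), 0.5, seed = 1)
  expect_length(sp4$train, 2)
  expect_equal(sum(c(0, 0, 1, 1)[sp4$test]), 1)

  expect_identical(stratified_split(y33, seed = 7),
                   stratified_split(y33, seed = 7))
  expect_error(stratified_split(c(0, 1, 1, 1)), "at least 2")
})

test_that("rank AUC matches hand cases and an independent implementation", {
  expect_equal(cmcmarkers:::auc_score(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(cmcmarkers:::auc_score(c(0, 0, 1, 1), c(4, 3, 2, 1)), 0)
  expect_equal(cmcmarkers:::auc_score(c(0, 1, 0, 1), c(1, 1, 1, 1)), 0.5)
  expect_equal(cmcmarkers:::auc_score(c(0, 1, 1, 0), c(1, 3, 2, 4)), 0.5)
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- rbinom(40, 1, 0.5)
  s <- rnorm(40) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(cmcmarkers:::auc_score(y, s), ref)
})

test_that("tuning fits a separable problem perfectly and deterministically", {
  tbl <- separable_table()
  sp <- stratified_split(tbl$group, 0.25, seed = 42)
  spec <- default_model_specs()$enet
  run <- tune_and_fit(spec, tbl[sp$train, ], tbl[sp$test, ], seed = 42)
  expect_equal(run$metrics$accuracy[run$metrics$split == "test"], 1)
  expect_equal(run$metrics$roc_auc[run$metrics$split == "test"], 1)
  expect_equal(sum(run$confusion$test), length(sp$test))
  expect_equal(sum(run$confusion$train), length(sp$train))

  run2 <- tune_and_fit(spec, tbl[sp$train, ], tbl[sp$test, ], seed = 42)
  expect_identical(run$best_params, run2$best_params)
  expect_identical(run$shap$train, run2$shap$train)

  # degenerate folds are refused
  bad <- tbl[c(1:10, 11:12), ]
  expect_error(
    tune_and_fit(spec, bad, tbl[sp$test, ], seed = 1, cv_folds = 3),
    "degenerate CV fold")
})

test_that("pure-noise labels give chance-level test AUC on average", {
  aucs <- vapply(1:15, function(s) {
    set.seed(s + 100)
    tbl <- tibble::tibble(group = rep(c(0, 1), each = 10))
    for (j in 1:5) tbl[[paste0("x", j)]] <- rnorm(20)
    sp <- stratified_split(tbl$group, 0.25, seed = s)
    run <- tune_and_fit(default_model_specs()$enet, tbl[sp$train, ],
                        tbl[sp$test, ], seed = s)
    run$metrics$roc_auc[run$metrics$split == "test"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.2)
  expect_lt(mean(aucs), 0.8)
})

test_that("every family produces an oriented margin and valid metrics", {
  tbl <- separable_table(n_per = 12, seed = 3)
  sp <- stratified_split(tbl$group, 0.25, seed = 42)
  for (spec in default_model_specs()) {
    run <- tune_and_fit(spec, tbl[sp$train, ], tbl[sp$test, ], seed = 42,
                        compute_shap = FALSE)
    te <- run$metrics[run$metrics$split == "test", ]
    expect_gte(te$roc_auc, 0.75)
    expect_true(all(unlist(te[c("accuracy", "precision", "recall", "f1",
                                "roc_auc")]) >= 0))
    expect_true(all(unlist(te[c("accuracy", "precision", "recall", "f1",
                                "roc_auc")]) <= 1))
  }
})

test_that("linear Shapley attributions are closed-form and additive", {
  tbl <- separable_table(n_per = 10, seed = 2)
  sp <- stratified_split(tbl$group, 0.25, seed = 42)
  run <- tune_and_fit(default_model_specs()$l2, tbl[sp$train, ],
                      tbl[sp$test, ], seed = 42)
  sh <- run$shap$train
  beta <- as.numeric(coef(run$model$fit, s = run$model$lambda))[-1]
  bg <- colMeans(run$x_train)
  expect_equal(sh, sweep(run$x_train, 2, bg) *
                 matrix(beta, nrow(sh), ncol(sh), byrow = TRUE))
  # additivity: attributions reconstruct margin differences
  m <- cmcmarkers:::predict_margin(run$model, run$x_train)
  m_bg <- cmcmarkers:::predict_margin(run$model, matrix(bg, 1))
  expect_equal(rowSums(sh), m - m_bg, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("tree and stump attributions reconstruct the margin", {
  tbl <- separable_table(n_per = 12, seed = 5)
  sp <- stratified_split(tbl$group, 0.25, seed = 42)
  for (fam in c("gbt", "ada")) {
    run <- tune_and_fit(default_model_specs()[[fam]], tbl[sp$train, ],
                        tbl[sp$test, ], seed = 42)
    m <- cmcmarkers:::predict_margin(run$model, run$x_test)
    sums <- rowSums(run$shap$test)
    # additive up to the per-model base value (TreeSHAP runs in float32)
    expect_lt(sd((m - sums)), 1e-4)
  }
})

test_that("kernel Shapley matches exhaustive Shapley on two features", {
  f <- function(m) 3 * m[, 1] + 2 * m[, 2] + 1.5 * m[, 1] * m[, 2]
  bg <- c(0.5, -1)
  x <- matrix(c(2, 1), 1, 2)
  # exact two-player Shapley values by coalition enumeration
  f00 <- f(matrix(bg, 1))
  f10 <- f(matrix(c(x[1], bg[2]), 1))
  f01 <- f(matrix(c(bg[1], x[2]), 1))
  f11 <- f(x)
  phi1 <- 0.5 * (f10 - f00) + 0.5 * (f11 - f01)
  phi2 <- 0.5 * (f01 - f00) + 0.5 * (f11 - f10)
  ks <- kernel_shap(f, x, bg, seed = 1)
  expect_equal(as.numeric(ks), c(phi1, phi2), tolerance = 1e-6)
  expect_equal(sum(ks), f11 - f00, tolerance = 1e-8)
})

test_that("feature consolidation counts non-zero runs and retains >= 4/6", {
  mk_run <- function(family, nz_cols, feats = paste0("f", 1:5)) {
    sh <- matrix(0, 4, length(feats), dimnames = list(NULL, feats))
    sh[, nz_cols] <- 1
    structure(list(family = family, feat_cols = feats,
                   shap = list(train = sh, test = sh)),
              class = "cmc_run")
  }
  runs <- c(lapply(1:3, function(i) mk_run("a", c(1, 2))),
            lapply(1:3, function(i) mk_run("b", c(1, 3))))
  rk <- consolidate_features(runs)
  expect_equal(rk$total[rk$feature == "f1"], 6)
  expect_true(rk$retained[rk$feature == "f1"])
  expect_equal(rk$total[rk$feature == "f2"], 3)
  expect_false(rk$retained[rk$feature == "f2"])  # strict >= 4
  expect_equal(rk$total[rk$feature == "f4"], 0)
  expect_error(consolidate_features(runs[1:5]), "exactly 6")
})

test_that("top-model selection ranks by mean AUC with sd tie-break", {
  s <- tibble::tibble(family = c("a", "b", "c"),
                      mean_auc = c(1, 1, 0.95), sd_auc = c(0, 0, 0))
  expect_equal(select_top_models(s), c("a", "b"))
  s2 <- tibble::tibble(family = c("a", "b", "c"),
                       mean_auc = c(0.9, 0.9, 0.9),
                       sd_auc = c(0.1, 0, 0.05))
  expect_equal(select_top_models(s2), c("b", "c"))
  expect_warning(one <- select_top_models(s[1, ]), "fewer than two")
  expect_equal(one, "a")
})

test_that("the 2-D embedding preserves duplicates and group structure", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40), 10, 4),
             matrix(rnorm(40, mean = 6), 10, 4))
  emb <- embed_2d(x)
  expect_equal(dim(emb), c(20L, 2L))
  expect_gt(silhouette_mean(emb, rep(c(0, 1), each = 10)), 0)

  xdup <- rbind(x, x[1, ])
  embd <- embed_2d(xdup)
  d <- sqrt(sum((embd[21, ] - embd[1, ])^2))
  expect_lt(d, 1e-6)
  expect_error(embed_2d(x[1:3, ]), "at least 4")
})
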