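# Group-stratified k-nearest-neighbour imputation with the neighbour count
# chosen by a one-sample t-test criterion.

# KNN-impute the numeric columns of one group's sub-table for a given k.
# Distances are Euclidean over mutually observed standardised features,
# scaled by the fraction observed (nan-aware Euclidean).
knn_impute_group <- function(x, k) {
  p <- ncol(x)
  mu <- vapply(x, function(col) mean(col, na.rm = TRUE), numeric(1))
  sg <- vapply(x, function(col) sd(col, na.rm = TRUE), numeric(1))
  sg[!is.finite(sg) | sg == 0] <- 1
  z <- sweep(sweep(as.matrix(x), 2, mu), 2, sg, "/")
  n <- nrow(z)
  obs <- !is.na(z)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    diffs <- sweep(z, 2, z[i, ])^2
    both <- obs & matrix(obs[i, ], n, p, byrow = TRUE)
    diffs[!both] <- 0
    cnt <- rowSums(both)
    d2[i, ] <- ifelse(cnt > 0, rowSums(diffs) * p / cnt, Inf)
  }
  out <- x
  capped <- FALSE
  for (j in seq_len(p)) {
    miss <- which(is.na(x[[j]]))
    if (!length(miss)) next
    donors_all <- which(!is.na(x[[j]]))
    if (!length(donors_all)) {
      stop("column entirely missing within a group: ", names(x)[j])
    }
    for (i in miss) {
      dd <- d2[i, donors_all]
      k_eff <- min(k, length(donors_all))
      if (k_eff < k) capped <- TRUE
      nn <- donors_all[order(dd)[seq_len(k_eff)]]
      out[i, j] <- mean(x[[j]][nn])
    }
  }
  attr(out, "capped") <- capped
  out
}

# Columns whose imputed values deviate from the pre-imputation group mean
# (one-sample t-test, p < 0.05); columns with a single imputed cell cannot
# be tested and are not counted.
count_deviating <- function(original, imputed) {
  dev <- 0L
  for (j in seq_len(ncol(original))) {
    miss <- is.na(original[[j]])
    if (sum(miss) < 2) next
    vals <- imputed[[j]][miss]
    if (sd(vals) == 0) {
      # degenerate t-test: deviating iff the constant differs from the mean
      ref <- mean(original[[j]], na.rm = TRUE)
      if (abs(vals[1] - ref) > 1e-12) dev <- dev + 1L
      next
    }
    p <- t.test(vals, mu = mean(original[[j]], na.rm = TRUE))$p.value
    if (is.finite(p) && p < 0.05) dev <- dev + 1L
  }
  dev
}

#' Group-stratified KNN imputation of the feature table
#'
#' Imputes missing feature cells separately within the stroke and healthy
#' subgroups using k-nearest neighbours over standardised mutually observed
#' features. `k` is selected from `k_grid` to minimise the number of
#' columns whose imputed values deviate significantly (one-sample t-test,
#' p < 0.05) from the pre-imputation group mean, with ties broken towards
#' the largest `k` (lower imputation variance).
#'
#' @param table A feature table from [extract_features()] (needs a `group`
#'   column coded 0 = stroke / 1 = healthy).
#' @param k_grid Candidate neighbour counts (default 1, 3, 5, 7, 9).
#' @return A `cmc_imputation` object: list with `data` (imputed tibble),
#'   `chosen_k`, and `deviation_report` (tibble of k vs deviating-column
#'   count). `tidy()` returns the report.
#' @export
impute_features <- function(table, k_grid = c(1, 3, 5, 7, 9)) {
  stopifnot("group" %in% names(table))
  num_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      "group")
  groups <- split(seq_len(nrow(table)), table$group)
  capped_any <- FALSE
  results <- lapply(k_grid, function(k) {
    imputed <- table
    dev <- 0L
    for (idx in groups) {
      sub <- table[idx, num_cols]
      filled <- knn_impute_group(sub, k)
      if (isTRUE(attr(filled, "capped"))) capped_any <<- TRUE
      imputed[idx, num_cols] <- filled
      dev <- dev + count_deviating(sub, filled)
    }
    list(data = imputed, dev = dev)
  })
  if (capped_any) {
    warning("a group had fewer donors than k; k was capped at group size - 1")
  }
  report <- tibble::tibble(k = k_grid,
                           n_deviating = vapply(results, `[[`, integer(1),
                                                "dev"))
  best <- which(report$n_deviating == min(report$n_deviating))
  chosen <- best[which.max(report$k[best])]
  structure(list(data = results[[chosen]]$data,
                 chosen_k = report$k[chosen],
                 deviation_report = report),
            class = "cmc_imputation")
}

#' @export
print.cmc_imputation <- function(x, ...) {
  cat(sprintf("<cmc_imputation: k = %d; deviating columns by k: %s>\n",
              x$chosen_k,
              paste(x$deviation_report$k, x$deviation_report$n_deviating,
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cmc_imputation <- function(x, ...) x$deviation_report
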