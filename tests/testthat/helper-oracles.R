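# Independent oracles and small fixtures used across the suite.

# O(n^2) brute-force sample-entropy template counter (Richman-Moorman
# convention, Chebyshev distance strictly below r, self-matches excluded).
sampen_oracle <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (db < r) {
        B <- B + 1
        if (max(db, abs(x[i + m] - x[j + m])) < r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Mean silhouette width for a 2-group labelling of points in a matrix.
silhouette_mean <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !own & seq_len(nrow(x)) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Small cohort with no missing trials, reused by feature-level tests.
tiny_cohort <- function(n_stroke = 2, n_healthy = 2, seed = 11,
                        missing = FALSE) {
  truth <- ground_truth(seed)
  if (!missing) truth$missing_prob$prob <- 0
  simulate_cohort(n_stroke, n_healthy, truth = truth)
}

# Separable two-informative-feature classification table.
separable_table <- function(n_per = 10, p_noise = 4, gap = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  tbl <- tibble::tibble(group = rep(c(0, 1), each = n_per))
  tbl$f1 <- rnorm(n) + gap * tbl$group
  tbl$f2 <- rnorm(n) - gap * tbl$group
  for (j in seq_len(p_noise)) tbl[[paste0("n", j)]] <- rnorm(n)
  tbl
}
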