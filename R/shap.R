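# Shapley-value attributions: exact closed forms for linear and additive
# models, TreeSHAP via xgboost's predcontrib for tree ensembles, and a
# sampling kernel estimator for black-box models (SVM).

# Rank-based ROC AUC of scores `s` for binary labels `y` (positive = 1).
auc_score <- function(y, s) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kernel Shapley attribution for a black-box prediction function
#'
#' Weighted-least-squares (kernel) estimator of Shapley values: coalitions
#' of features are drawn with Shapley kernel weights, absent features are
#' replaced by a background row, and attributions solve the constrained
#' regression so that they sum exactly to `f(x) - f(background)`. With 10
#' or fewer features all coalitions are enumerated and the result is exact.
#'
#' @param f Function mapping a numeric matrix of rows to predictions
#'   (margins).
#' @param x Matrix of rows to explain.
#' @param background Single background row (numeric vector), typically the
#'   training-feature means.
#' @param nsim Number of sampled coalitions when enumeration is infeasible.
#' @param seed RNG seed for coalition sampling.
#' @return Matrix of attributions, same shape as `x`.
#' @export
kernel_shap <- function(f, x, background, nsim = 1024, seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(length(background) == p, p >= 2)
  f0 <- as.numeric(f(matrix(background, 1)))

  build_z <- function() {
    if (p <= 10) {
      sizes <- 1:(p - 1)
      z <- as.matrix(expand.grid(rep(list(0:1), p)))
      z <- z[rowSums(z) %in% sizes, , drop = FALSE]
      s <- rowSums(z)
      w <- (p - 1) / (choose(p, s) * s * (p - s))
      list(z = z, w = w)
    } else {
      sizes <- 1:(p - 1)
      pr <- (p - 1) / (sizes * (p - sizes))
      pr <- pr / sum(pr)
      s <- sample(sizes, nsim, replace = TRUE, prob = pr)
      z <- matrix(0L, nsim, p)
      for (k in seq_len(nsim)) z[k, sample.int(p, s[k])] <- 1L
      list(z = z, w = rep(1, nsim))
    }
  }
  zw <- with_seed(seed, build_z())
  z <- zw$z
  w <- zw$w
  m <- nrow(z)

  out <- matrix(0, nrow(x), p, dimnames = dimnames(x))
  bg <- matrix(background, m, p, byrow = TRUE)
  for (i in seq_len(nrow(x))) {
    xi <- matrix(x[i, ], m, p, byrow = TRUE)
    y <- as.numeric(f(z * xi + (1 - z) * bg))
    fx <- as.numeric(f(x[i, , drop = FALSE]))
    zp <- z[, p]
    zt <- sweep(z[, -p, drop = FALSE], 1, zp)
    yt <- y - f0 - zp * (fx - f0)
    A <- crossprod(zt * w, zt) + diag(1e-8, p - 1)
    b <- crossprod(zt * w, yt)
    phi <- as.numeric(solve(A, b))
    out[i, ] <- c(phi, fx - f0 - sum(phi))
  }
  out
}
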