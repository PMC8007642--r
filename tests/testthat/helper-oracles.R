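# Independent oracles used to cross-check the estimators.  These are
# deliberately written with explicit arithmetic (loops, element sums,
# closed-form normal equations) rather than the matrix/QR routes the
# package uses.

# weighted regression through the origin: beta and fixed-effects se
oracle_ivw <- function(x, y, sy) {
  w <- 1 / sy^2
  num <- 0
  den <- 0
  for (j in seq_along(x)) {
    num <- num + w[j] * x[j] * y[j]
    den <- den + w[j] * x[j]^2
  }
  list(beta = num / den, se = 1 / sqrt(den))
}

# weighted two-parameter regression via the 2x2 normal equations solved
# by Cramer's rule
oracle_egger <- function(x, y, sy) {
  s <- sign(x)
  x <- abs(x)
  y <- y * s
  w <- 1 / sy^2
  sw <- sum(w)
  swx <- sum(w * x)
  swxx <- sum(w * x^2)
  swy <- sum(w * y)
  swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  a <- (swxx * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  list(intercept = a, slope = b,
       se_intercept = sqrt(swxx / det), se_slope = sqrt(sw / det))
}

# K-exposure weighted normal equations solved explicitly
oracle_mvmr <- function(B, y, sy) {
  w <- 1 / sy^2
  K <- ncol(B)
  A <- matrix(0, K, K)
  b <- numeric(K)
  for (j in seq_along(y)) {
    A <- A + w[j] * tcrossprod(B[j, ])
    b <- b + w[j] * B[j, ] * y[j]
  }
  Ainv <- solve(A)
  list(coef = drop(Ainv %*% b), se = sqrt(diag(Ainv)))
}

# exhaustive weighted-CDF interpolation for the weighted median
oracle_weighted_median <- function(v, w) {
  ord <- order(v)
  v <- v[ord]
  w <- w[ord] / sum(w)
  cum <- numeric(length(w))
  run <- 0
  for (j in seq_along(w)) {
    cum[j] <- run + w[j] / 2
    run <- run + w[j]
  }
  if (0.5 <= cum[1]) return(v[1])
  if (0.5 >= cum[length(cum)]) return(v[length(v)])
  k <- which(cum >= 0.5)[1]
  v[k - 1] + (v[k] - v[k - 1]) * (0.5 - cum[k - 1]) / (cum[k] - cum[k - 1])
}

# fine-grid maximiser of the weighted normal-kernel density of ratios
oracle_mode <- function(ratio, w, bw, n_grid = 200001) {
  w <- w / sum(w)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = n_grid)
  dens <- vapply(grid, function(g) sum(w * dnorm((g - ratio) / bw)),
                 numeric(1))
  grid[which.max(dens)]
}

# weighted residual sum of squares by explicit summation
oracle_q <- function(x, y, sy, beta, intercept = 0) {
  sum((y - intercept - beta * x)^2 / sy^2)
}

# build a tiny association table by hand
toy_table <- function(ids, a1, a2, eaf, beta, se, n = 1e5,
                      trait = "trait", pvalue = NULL) {
  data.frame(variant_id = ids, effect_allele = a1, other_allele = a2,
             eaf = eaf, beta = beta, se = se,
             pvalue = if (is.null(pvalue)) 2 * pnorm(-abs(beta / se))
                      else pvalue,
             n = n, trait_id = trait, pvalue_derived = FALSE,
             stringsAsFactors = FALSE)
}

# harmonised set for estimator tests without the harmonisation machinery
toy_harmonised <- function(bx, by, sx, sy, ld = NULL, ids = NULL) {
  J <- length(bx)
  ids <- ids %||% sprintf("rs%d", seq_len(J))
  ex <- toy_table(ids, "A", "G", rep(0.3, J), bx, sx, trait = "X")
  out <- toy_table(ids, "A", "G", rep(0.3, J), by, sy, trait = "Y")
  suppressMessages(harmonise(ex, out, ld = ld))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
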