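# Independent oracles used to validate the package's computations.
# Each is a deliberately naive implementation (normal equations, grid
# search, numerical integration) sharing no code with the package.

# OLS by the normal equations.
ols_bruteforce <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Johnson-Neyman boundaries by brute-force pointwise t tests on a grid:
# returns x values where |t| crosses the critical value.
ros_grid_oracle <- function(b2, b3, v22, v33, v23, df, alpha = 0.05,
                            lo = -10, hi = 10, step = 1e-4) {
  xs <- seq(lo, hi, by = step)
  tcrit <- qt(1 - alpha / 2, df)
  tv <- (b2 + b3 * xs) / sqrt(v22 + xs^2 * v33 + 2 * xs * v23)
  sig <- abs(tv) > tcrit
  flips <- which(diff(sig) != 0)
  (xs[flips] + xs[flips + 1L]) / 2
}

# PoI by numerical integration of the absolute between-line gap on each
# side of the crossover (trapezoid rule).
poi_integration_oracle <- function(b2, b3, lo, hi, right_better = TRUE,
                                   n_points = 1e5) {
  gap <- function(x) abs(b2 + b3 * x)
  trapz <- function(a, b) {
    if (b <= a) return(0)
    xs <- seq(a, b, length.out = n_points)
    sum((gap(xs[-1]) + gap(xs[-length(xs)])) / 2 * diff(xs))
  }
  xc <- min(max(-b2 / b3, lo), hi)
  right <- trapz(xc, hi)
  left <- trapz(lo, xc)
  if (right_better) right / (right + left) else left / (right + left)
}

# Exhaustive two-stage grid search over the 3-simplex for the 2-SNP
# haplotype-frequency MLE.  Haplotype order: 00, 10, 01, 11 in risk-allele
# coding at (snp1, snp2).
em_grid_oracle_2snp <- function(dosages, coarse = 0.01, fine = 5e-4) {
  pats <- unique(dosages)
  key <- apply(dosages, 1, paste, collapse = ",")
  pkey <- apply(pats, 1, paste, collapse = ",")
  w <- as.numeric(table(factor(key, levels = pkey)))
  H <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  pairs <- lapply(seq_len(nrow(pats)), function(i) {
    g <- pats[i, ]
    out <- NULL
    for (a in 1:4) for (b in a:4) {
      if (all(H[a, ] + H[b, ] == g)) out <- rbind(out, c(a, b))
    }
    out
  })
  loglik <- function(F) {
    # F: matrix n_grid x 4
    ll <- 0
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      p <- 0
      for (j in seq_len(nrow(pr))) {
        a <- pr[j, 1]; b <- pr[j, 2]
        p <- p + (2 - (a == b)) * F[, a] * F[, b]
      }
      ll <- ll + w[i] * log(p)
    }
    ll
  }
  grid_simplex <- function(center, half, step) {
    sq <- function(c0) seq(max(0, c0 - half), min(1, c0 + half), by = step)
    g <- expand.grid(f1 = sq(center[1]), f2 = sq(center[2]),
                     f3 = sq(center[3]))
    g$f4 <- 1 - g$f1 - g$f2 - g$f3
    g <- g[g$f4 >= -1e-12 & g$f4 <= 1 + 1e-12, ]
    g$f4 <- pmax(g$f4, 0)
    as.matrix(g)
  }
  F1 <- grid_simplex(c(0.5, 0.5, 0.5), 0.5, coarse)
  best <- F1[which.max(loglik(F1)), ]
  F2 <- grid_simplex(best[1:3], 2 * coarse, fine)
  F2[which.max(loglik(F2)), ]
}

# Random plausible interaction fits: coefficients on the scale of trait
# outcomes, positive-definite covariance from a random square root.
random_fit <- function() {
  b <- c(runif(1, 10, 90), runif(1, -5, 5), runif(1, -10, 10),
         runif(1, -15, -2))
  A <- matrix(rnorm(16, sd = c(2, 1, 1.5, 2)), 4, 4)
  V <- crossprod(A) + diag(1e-3, 4)
  df <- sample(50:500, 1)
  as_gxe_fit(b[1], b[2], b[3], b[4], vcov = V, df = df, n = df + 4)
}

# Fast OLS fit of y ~ x + z + x:z returning b3's estimate, SE and p-value
# (used to keep the calibration loops cheap).
fast_gxe_b3 <- function(x, z, y) {
  X <- cbind(1, x, z, x * z)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - 4L
  s2 <- sum(res^2) / df
  se3 <- sqrt(s2 * solve(XtX)[4, 4])
  t3 <- b[4] / se3
  c(b3 = b[4], se = se3, p = 2 * pt(-abs(t3), df))
}
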