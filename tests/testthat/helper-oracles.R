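# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# random symmetric positive-definite tensor with diffusivities ~1e-3 mm^2/s
random_spd_tensor <- function() {
  A <- matrix(rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.1
  S * (1e-3 / mean(diag(S)))
}

# brute-force lattice enumeration of a sphere mask
sphere_count_oracle <- function(diameter_mm, voxel_size_mm) {
  r <- diameter_mm / 2
  rng <- lapply(voxel_size_mm, function(v) seq(-ceiling(r / v), ceiling(r / v)))
  n <- 0L
  for (i in rng[[1]]) {
    for (j in rng[[2]]) {
      for (k in rng[[3]]) {
        d2 <- (i * voxel_size_mm[1])^2 + (j * voxel_size_mm[2])^2 +
          (k * voxel_size_mm[3])^2
        if (d2 <= r^2 + 1e-12) n <- n + 1L
      }
    }
  }
  n
}

# Benjamini-Hochberg step-up by its definition: q_(i) = min_{j>=i} p_(j)*m/j
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    q_sorted[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# residualize-then-correlate partial correlation, coded independently
pcor_oracle <- function(x, y, Z = NULL, method = "pearson") {
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
    if (!is.null(Z)) Z <- apply(as.matrix(Z), 2, rank)
  }
  M <- cbind(1, Z)
  H <- M %*% solve(t(M) %*% M) %*% t(M)
  rx <- x - H %*% x
  ry <- y - H %*% y
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  k <- ncol(M) - 1L
  df <- length(x) - k - 2L
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = df))
}

# textbook pooled-variance two-sample t
pooled_t_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

# Mann-Whitney U by exhaustive pair enumeration (ties counted 1/2)
mwu_oracle <- function(x, y) {
  u <- 0
  for (xi in x) {
    u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  }
  u
}

# slope-equality t recomputed from raw sums (normal equations), independent
# of lm()
slope_test_oracle <- function(x1, y1, x2, y2) {
  comp <- function(x, y) {
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    ss_res <- sum((y - a - b * x)^2)
    se <- sqrt(ss_res / (n - 2) / sxx)
    list(b = b, se = se, n = n)
  }
  f1 <- comp(x1, y1)
  f2 <- comp(x2, y2)
  tt <- (f1$b - f2$b) / sqrt(f1$se^2 + f2$se^2)
  df <- f1$n + f2$n - 4
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df = df))
}
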