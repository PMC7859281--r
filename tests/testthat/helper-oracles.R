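# Independent oracles used across the suite.  Each is implemented directly
# from the defining formula, separately from the package code paths it
# checks.

# Benjamini-Hochberg step-up, from the order-statistic definition:
# adjusted_(i) = min_{j >= i} m * p_(j) / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# partial correlation of x and y given Z from the precision matrix of
# (x, y, Z): r = -Omega_12 / sqrt(Omega_11 * Omega_22)
partial_cor_precision_oracle <- function(x, y, Z) {
  S <- stats::cov(cbind(x, y, Z))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# first-order Markov transition frequencies by direct counting
count_transitions_oracle <- function(s, k) {
  counts <- matrix(0, k, k)
  for (t in seq_len(length(s) - 1L))
    counts[s[t + 1L], s[t]] <- counts[s[t + 1L], s[t]] + 1
  counts
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# amplitude of a sinusoid of known frequency in a series (least squares)
fitted_amplitude <- function(x, freq_hz, tr) {
  t <- (seq_along(x) - 1) * tr
  fit <- stats::lm(x ~ sin(2 * pi * freq_hz * t) + cos(2 * pi * freq_hz * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# n points around each of k Gaussian cloud centres; returns x and labels
make_clouds <- function(centres, n_per, sd = 0.2) {
  k <- nrow(centres)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(stats::rnorm(n_per * ncol(centres), sd = sd),
                 n_per, ncol(centres)), 2, centres[i, ], "+")))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# small synthetic scan: two-component time courses under one covariance
toy_tc <- function(n = 60, C = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  component_tc(matrix(stats::rnorm(n * C), n, C), scan_id = "toy")
}

# explicit monomial feature map of the inhomogeneous polynomial kernel in
# 2 dimensions: (1 + u1 v1 + u2 v2)^p expanded by multinomial theorem
poly_feature_map <- function(u, p) {
  stopifnot(length(u) == 2L)
  feats <- c()
  for (a in 0:p) for (b in 0:(p - a)) {
    cfac <- factorial(p) / (factorial(a) * factorial(b) * factorial(p - a - b))
    feats <- c(feats, sqrt(cfac) * u[1]^a * u[2]^b)
  }
  feats
}
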