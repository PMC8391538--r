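# Independent oracles, deliberately naive: element-wise double loops and
# direct enumeration, kept free of any code path they are used to check.

oracle_gauss_kernel <- function(x, y, l) exp(-sum((x - y)^2) / (2 * l^2))

# Brute-force V-statistic MMD^2: three explicit double sums.
oracle_mmd2 <- function(X, Y, l) {
  m <- nrow(X); n <- nrow(Y)
  s_xx <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    s_xx <- s_xx + oracle_gauss_kernel(X[i, ], X[j, ], l)
  }
  s_yy <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s_yy <- s_yy + oracle_gauss_kernel(Y[i, ], Y[j, ], l)
  }
  s_xy <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s_xy <- s_xy + oracle_gauss_kernel(X[i, ], Y[j, ], l)
  }
  s_xx / m^2 + s_yy / n^2 - 2 * s_xy / (m * n)
}

# All pairwise Euclidean distances of the rows of a matrix, by enumeration.
oracle_pairwise_distances <- function(P) {
  n <- nrow(P)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out <- c(out, sqrt(sum((P[i, ] - P[j, ])^2)))
  }
  out
}

# Direct sampler of the noise difference Z = Lap(b) - Lap(2b) using R's
# exponential generator (independent of the package's inverse-CDF sampler).
oracle_noise_diff <- function(n, b) {
  lap <- function(n, s) (stats::rexp(n, 1 / s) - stats::rexp(n, 1 / s))
  lap(n, b) - lap(n, 2 * b)
}

random_dataset <- function(n, d, spread = 1) {
  matrix(stats::rnorm(n * d, sd = spread), ncol = d)
}
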