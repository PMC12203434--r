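# Independent oracles and geometry helpers shared across the suite.
# Every oracle re-derives its quantity from first principles (explicit
# loops, closed forms) without touching the code paths it checks.

# mass-weighted mean position, written as an explicit loop
com_oracle <- function(elements, xyz) {
  num <- c(0, 0, 0)
  den <- 0
  for (i in seq_along(elements)) {
    w <- atomic_mass(elements[i])
    num <- num + w * xyz[i, ]
    den <- den + w
  }
  num / den
}

# half of each pair energy to each atom, explicit double loop
half_sum_oracle <- function(pairs) {
  n <- nrow(pairs)
  eps <- numeric(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b) eps[a] <- eps[a] + 0.5 * pairs[a, b]
    }
  }
  eps
}

# total pair energy, explicit double loop over unique pairs
total_oracle <- function(pairs) {
  n <- nrow(pairs)
  tot <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) tot <- tot + pairs[a, b]
  }
  tot
}

# simple-linear-regression coefficients from the closed-form normal equations
normal_equations_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# random orthogonal matrix (proper rotation), deterministic under the
# caller's seed
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  scale <- max(abs(expected), .Machine$double.eps)
  expect_lt(abs(actual - expected) / scale, rel_tol)
}
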