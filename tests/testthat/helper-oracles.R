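# Independent brute-force oracles used to verify the package's
# implementations. Deliberately naive and separate from the package code.

# Mann-Whitney AUC by explicit enumeration of all case/control pairs.
pairs_auc_oracle <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  cmp <- outer(s1, s0, `>`) + 0.5 * outer(s1, s0, `==`)
  mean(cmp)
}

# Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# geNORM M by a double loop over candidate pairs.
genorm_oracle <- function(l) {
  p <- ncol(l)
  m <- numeric(p)
  for (j in seq_len(p)) {
    sds <- numeric(0)
    for (k in seq_len(p)) {
      if (k == j) next
      sds <- c(sds, sd(l[, j] - l[, k]))
    }
    m[j] <- mean(sds)
  }
  m
}

# NormFinder rho recomputed step by step from its definition.
normfinder_oracle <- function(l, groups) {
  centred <- l - rowMeans(l)
  glev <- sort(unique(groups))
  p <- ncol(l)
  rho <- numeric(p)
  for (g in seq_len(p)) {
    v <- w <- n <- numeric(length(glev))
    for (i in seq_along(glev)) {
      xs <- centred[groups == glev[i], g]
      v[i] <- mean(xs)
      w[i] <- var(xs)
      n[i] <- length(xs)
    }
    d <- v - mean(v)
    rho[g] <- mean(abs(d) + sqrt(w / n))
  }
  rho
}

# Wilson interval from the closed-form quadratic in p:
# (p - c)^2 <= z^2 c (1 - c) / n  solved for the centre c.
wilson_oracle <- function(s, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- s / n
  disc <- sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c((p + z^2 / (2 * n) - z * disc) / (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * disc) / (1 + z^2 / n))
}

# Simple-regression slope/intercept from the closed-form normal equations.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Exhaustive best subset of a given size under a criterion function.
exhaustive_best <- function(p, size, crit_fn) {
  combs <- utils::combn(p, size)
  vals <- apply(combs, 2, crit_fn)
  list(idx = combs[, which.max(vals)], value = max(vals))
}
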