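# Independent oracles used to cross-check the implementation. These stay
# deliberately naive and share no code path with the package.

# Noncentral-F upper tail as a Poisson(ncp/2) mixture of *central* F tails
# with shifted numerator df. Independent of R's pf(..., ncp=) code path.
ncf_upper_tail_series <- function(x, df1, df2, ncp, tol = 1e-14) {
  lambda <- ncp / 2
  total <- 0
  jmax <- max(200, ceiling(lambda + 20 * sqrt(lambda) + 50))
  for (j in 0:jmax) {
    wj <- stats::dpois(j, lambda)
    total <- total + wj * stats::pf(x * df1 / (df1 + 2 * j), df1 + 2 * j, df2,
                                    lower.tail = FALSE)
    if (j > lambda && wj < tol) break
  }
  total
}

power_oracle <- function(p, n1, n2, ncp, alpha) {
  df2 <- n1 + n2 - p - 1
  ncf_upper_tail_series(stats::qf(1 - alpha, p, df2), p, df2, ncp)
}

# Brute-force T^2 via eigen-decomposed inverse of the pooled covariance.
t2_brute <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  S <- ((n1 - 1) * cov(X1) + (n2 - 1) * cov(X2)) / (n1 + n2 - 2)
  eg <- eigen(S, symmetric = TRUE)
  Sinv <- eg$vectors %*% diag(1 / eg$values, nrow = length(eg$values)) %*% t(eg$vectors)
  d <- colMeans(X1) - colMeans(X2)
  as.numeric((n1 * n2 / (n1 + n2)) * t(d) %*% Sinv %*% d)
}

# Pillai trace via eigenvalues of (H+E)^{-1} H.
pillai_eigen_oracle <- function(H, E) {
  sum(Re(eigen(solve(H + E) %*% H, only.values = TRUE)$values))
}

# One-way between-group / total SS by direct group-mean arithmetic.
ss_oneway_oracle <- function(y, g) {
  g <- as.factor(g)
  gm <- tapply(y, g, mean)
  n <- tapply(y, g, length)
  list(between = sum(n * (gm - mean(y))^2), total = sum((y - mean(y))^2))
}
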