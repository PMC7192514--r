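# Independent oracle: composite log-likelihood by brute-force double loop
# over gene pairs, evaluating each bivariate normal density through the
# generic matrix route (det/solve on the 2x2 covariance) rather than the
# closed-form v/c expression used by the package.
naive_composite_loglik <- function(y, powers, theta, d = NULL) {
  if (!is.list(powers)) powers <- list(powers)
  m <- length(y)
  v <- theta$sigma2[1]
  ll <- 0
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      cij <- 0
      for (k in seq_along(powers))
        cij <- cij + theta$sigma2[k + 1] * powers[[k]][i, j]
      if (!is.null(d)) cij <- cij + theta$sigma2_d * d[i, j]
      S <- matrix(c(v, cij, cij, v), 2)
      z <- c(y[i] - theta$mu, y[j] - theta$mu)
      ll <- ll - log(2 * pi) - 0.5 * log(det(S)) -
        0.5 * sum(z * solve(S, z))
    }
  }
  ll
}

# Random Erdos-Renyi-style binary symmetric zero-diagonal adjacency.
random_adjacency <- function(m, p_edge = 0.3) {
  U <- matrix(stats::runif(m * m) < p_edge, m, m)
  U[lower.tri(U, diag = TRUE)] <- FALSE
  A <- (U | t(U)) * 1
  Matrix::Matrix(A, sparse = TRUE)
}

# Random valid parameter set for a given set of powers: variance components
# scaled so every pair covariance stays strictly inside (-sigma0^2, sigma0^2).
random_theta <- function(powers, with_d = FALSE) {
  if (!is.list(powers)) powers <- list(powers)
  K <- length(powers)
  s0 <- 0.5 + stats::runif(1)
  caps <- vapply(powers, function(P) max(abs(P)), numeric(1))
  caps[caps == 0] <- 1
  s <- stats::runif(K) * 0.6 * s0 / (caps * (K + with_d))
  list(mu = stats::rnorm(1, 0, 0.3), sigma2 = c(s0, s),
       sigma2_d = if (with_d) stats::runif(1) * 0.2 * s0)
}

# Brute-force count of 2-paths between every gene pair.
count_two_paths <- function(A) {
  A <- as.matrix(A)
  m <- nrow(A)
  P <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) for (h in 1:m)
    if (h != i && h != j) P[i, j] <- P[i, j] + A[i, h] * A[h, j]
  diag(P) <- 0
  P
}
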