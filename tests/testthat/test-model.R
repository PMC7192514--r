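test_that("pair log-density matches closed forms and the matrix-route oracle", {
  expect_equal(pair_loglik(0, 0, 1, 0), -log(2 * pi))
  expect_equal(pair_loglik(1, 1, 1, 0), -log(2 * pi) - 1)
  S <- matrix(c(1, 0.3, 0.3, 1), 2); z <- c(0.5, -0.2)
  ref <- -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * sum(z * solve(S, z))
  expect_equal(pair_loglik(0.5, -0.2, 1, 0.3), ref)
  expect_identical(pair_loglik(0, 0, 1, 1), -Inf)   # degenerate covariance
  expect_error(pair_loglik(0, 0, -1, 0), "positive")
})

test_that("pair grouping partitions all unordered pairs with exact statistics", {
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(3, 3))
  y <- c(1, 2, 3)
  g <- build_pair_groups(y, A)
  expect_s3_class(g, "pair_groups")
  expect_equal(sum(g$n_pairs), 3)
  expect_equal(g$n_pairs[g$patterns[, 1] == 1], 1)
  expect_equal(g$n_pairs[g$patterns[, 1] == 0], 2)
  # connected-group statistics are the pair {1,2}
  e <- which(g$patterns[, 1] == 1)
  expect_equal(g$S1[e], 3); expect_equal(g$S2[e], 5); expect_equal(g$S12[e], 2)
  set.seed(21)
  for (r in 1:10) {
    m <- sample(5:25, 1)
    g <- build_pair_groups(rnorm(m), random_adjacency(m))
    expect_equal(sum(g$n_pairs), m * (m - 1) / 2)
  }
})

test_that("grouped composite likelihood equals the naive pairwise sum", {
  set.seed(22)
  for (r in 1:15) {
    m <- sample(6:12, 1)
    K <- sample(1:3, 1)
    A <- random_adjacency(m)
    powers <- lapply(1:K, function(k) matrix_power_zero_diag(A, k))
    y <- rnorm(m)
    th <- random_theta(powers)
    g <- build_pair_groups(y, powers)
    expect_equal(composite_loglik(th, g),
                 naive_composite_loglik(y, powers, th), tolerance = 1e-12)
  }
})

test_that("exact-mode distance grouping reproduces the naive sum", {
  set.seed(23)
  for (r in 1:8) {
    m <- sample(6:12, 1)
    A <- random_adjacency(m)
    D <- matrix(runif(m * m), m); D <- (D + t(D)) / 2; diag(D) <- 0
    y <- rnorm(m)
    th <- random_theta(A, with_d = TRUE)
    g <- build_pair_groups(y, A, d = D, d_mode = "exact")
    expect_equal(composite_loglik(th, g),
                 naive_composite_loglik(y, A, th, d = D), tolerance = 1e-12)
  }
})

test_that("with no network variance the likelihood factorizes into univariate terms", {
  set.seed(24)
  m <- 30
  y <- rnorm(m)
  g <- build_pair_groups(y, random_adjacency(m))
  th <- list(mu = 0.2, sigma2 = c(1.3, 0))
  expect_equal(composite_loglik(th, g),
               (m - 1) * sum(dnorm(y, 0.2, sqrt(1.3), log = TRUE)))
  # single independent pair at the mode
  g2 <- build_pair_groups(c(0, 0), Matrix::Matrix(0, 2, 2, sparse = TRUE))
  expect_equal(composite_loglik(list(mu = 0, sigma2 = c(1, 0)), g2),
               -log(2 * pi))
})

test_that("composite likelihood is invariant to consistent gene permutation", {
  set.seed(25)
  m <- 15
  A <- random_adjacency(m)
  y <- rnorm(m)
  th <- random_theta(A)
  perm <- sample(m)
  ll1 <- composite_loglik(th, build_pair_groups(y, A))
  ll2 <- composite_loglik(th, build_pair_groups(y[perm], A[perm, perm]))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("invalid pattern covariance yields -Inf", {
  A <- random_adjacency(6, 0.5)
  g <- build_pair_groups(rnorm(6), A)
  expect_identical(composite_loglik(list(mu = 0, sigma2 = c(0.5, 0.6)), g), -Inf)
})

test_that("fit recovers signal direction and flags empty networks", {
  set.seed(26)
  A <- generate_block_adjacency(400, 8:10)
  y <- simulate_outcome(A, 0.1)
  f <- coconet(y, A)
  expect_s3_class(f, "coconet")
  expect_true(f$converged)
  expect_gt(f$rho, 0.01)
  expect_lt(f$rho, 1)
  expect_true(is.finite(f$loglik))
  # null data: rho_hat collapses toward zero
  rhos <- replicate(5, {
    yy <- rnorm(400)
    coconet(yy, A)$rho
  })
  expect_lt(median(rhos), 0.01)
  # no-edge adjacency: sigma1 unidentifiable, reported 0 with warning
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(50, 50))
  expect_warning(f0 <- coconet(rnorm(50), A0), "no edges")
  expect_equal(unname(coef(f0)["sigma1_sq"]), 0)
  expect_equal(f0$rho, 0)
})

test_that("fit methods are coherent with the stored parameters", {
  set.seed(27)
  A <- generate_block_adjacency(150, 4:6)
  y <- simulate_outcome(A, 0.2)
  f <- coconet(y, A)
  expect_equal(unname(coef(f)["mu"]), f$theta$mu)
  expect_equal(as.numeric(logLik(f)), f$loglik)
  expect_equal(attr(logLik(f), "nobs"), f$n_pairs)
  expect_equal(BIC(f), -2 * f$loglik + 3 * log(f$n_pairs))
  expect_equal(BIC(f, convention = "genes"),
               -2 * f$loglik + 3 * log(150))
  expect_equal(residuals(f), y - f$theta$mu)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(150, 3))
  expect_equal(simulate(f, nsim = 3, seed = 1), sims)  # seed reproducibility
})

test_that("BIC formula matches its definition and preserves likelihood ordering", {
  # loglik 0, 3 parameters, 100 observations
  f <- structure(list(loglik = 0, n_params = 3, n_pairs = 100, m = 15),
                 class = "coconet")
  expect_equal(BIC(f), 3 * log(100))
  set.seed(28)
  y <- rnorm(100)
  fits <- lapply(1:4, function(i) coconet(y, random_adjacency(100, 0.05)))
  ll <- sapply(fits, function(f) f$loglik)
  bb <- sapply(fits, BIC)
  expect_equal(order(-ll), order(bb))
})
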