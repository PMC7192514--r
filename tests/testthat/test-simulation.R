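test_that("block adjacency from explicit labels gives complete blocks", {
  A <- generate_block_adjacency(6, labels = c(1, 1, 1, 2, 2, 2))
  expect_equal(sum(A) / 2, 6)  # 2 * choose(3, 2)
  expect_equal(as.matrix(A[1:3, 1:3]), matrix(1, 3, 3) - diag(3),
               ignore_attr = TRUE)
  expect_true(all(A[1:3, 4:6] == 0))
})

test_that("random block adjacency satisfies the adjacency contract", {
  set.seed(41)
  for (r in 1:5) {
    A <- generate_block_adjacency(80, 4:8)
    expect_true(Matrix::isSymmetric(A, checkDN = FALSE))
    expect_true(all(Matrix::diag(A) == 0))
    expect_true(all(A@x %in% c(0, 1)))
  }
  expect_error(generate_block_adjacency(10, 11:12), "cluster_range")
})

test_that("complete-block adjacency has smallest eigenvalue -1", {
  A <- generate_block_adjacency(30, labels = rep(1:3, each = 10))
  ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), -1, tolerance = 1e-10)
  # hence sigma1^2 A + sigma0^2 I is positive definite iff sigma1^2 < sigma0^2
  expect_error(simulate_outcome(A, 0.5), "positive definite")
})

test_that("simulated outcomes have the model's marginal moments", {
  set.seed(42)
  y0 <- simulate_outcome(generate_block_adjacency(2000, 10:15), 0)
  expect_equal(mean(y0), 0, tolerance = 0.08)
  expect_equal(var(y0), 1, tolerance = 0.1)  # rho = 0: iid standard normal
  A <- generate_block_adjacency(60, labels = rep(1:2, each = 30))
  draws <- replicate(4000, simulate_outcome(A, 0.02))
  C <- cov(t(draws))
  within <- as.matrix(A) == 1
  expect_lt(abs(mean(C[within]) - 0.02), 0.002)  # ~3 MC sd at 4000 draws
  expect_equal(mean(diag(C)), 0.98, tolerance = 0.02)
  off <- !within & !diag(60)
  expect_equal(mean(C[off]), 0, tolerance = 0.006)
})

test_that("scenario II removes and adds edges with preserved expected count", {
  set.seed(43)
  A <- generate_block_adjacency(50, 3:5)
  expect_identical(perturb_scenario2(A, 0), A)
  B <- perturb_scenario2(A, 0.3)
  expect_true(Matrix::isSymmetric(B, checkDN = FALSE))
  expect_true(all(Matrix::diag(B) == 0))
  # p = 1: no original edge survives
  B1 <- perturb_scenario2(A, 1)
  expect_equal(sum((A == 1) & (B1 == 1)), 0)
})

test_that("scenario III only adds edges and keeps the truth as a subgraph", {
  set.seed(44)
  A <- generate_block_adjacency(40, 3:5)
  expect_identical(perturb_scenario3(A, 0), A)
  for (q in c(0.1, 0.5)) {
    B <- perturb_scenario3(A, q)
    expect_true(all(as.matrix(B) >= as.matrix(A)))  # containment
    expect_true(Matrix::isSymmetric(B, checkDN = FALSE))
  }
  Bfull <- perturb_scenario3(A, 1)
  expect_equal(sum(Bfull) / 2, 40 * 39 / 2)  # complete graph, no self-loops
})

test_that("power experiments are exactly reproducible under a fixed seed", {
  s1 <- run_power_experiment("I", rho = 0.3, m = 60, n_tissues = 3,
                             cluster_range = 3:4, n_replicates = 5, seed = 9)
  s2 <- run_power_experiment("I", rho = 0.3, m = 60, n_tissues = 3,
                             cluster_range = 3:4, n_replicates = 5, seed = 9)
  expect_identical(s1$replicates, s2$replicates)
  expect_equal(s1$power, mean(s1$replicates$correct))
  expect_equal(nrow(s1$replicates), 5)
  # extending the replicate count leaves earlier replicates unchanged
  s3 <- run_power_experiment("I", rho = 0.3, m = 60, n_tissues = 3,
                             cluster_range = 3:4, n_replicates = 8, seed = 9)
  expect_identical(s3$replicates[1:5, ], s1$replicates)
})

test_that("power increases with signal strength at small scale", {
  pw <- sapply(c(0, 0.08), function(rho)
    run_power_experiment("I", rho = rho, m = 300, n_tissues = 5,
                         cluster_range = 6:8, n_replicates = 30,
                         seed = 10)$power)
  expect_gt(pw[2], pw[1] + 0.2)
})
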