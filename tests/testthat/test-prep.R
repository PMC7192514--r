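test_that("standardize_effects scales by SNP count then standardizes", {
  y <- standardize_effects(c(1, 4, 9), c(1, 2, 3))
  expect_equal(unname(y), c(-1, 0, 1))
  set.seed(11)
  h2 <- rexp(20); ns <- sample(10:500, 20)
  y <- standardize_effects(h2, ns)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(sd(y), 1, tolerance = 1e-12)
})

test_that("standardize_effects rejects degenerate and invalid input", {
  expect_error(standardize_effects(c(2, 4), c(1, 2)), "zero variance")
  expect_error(standardize_effects(c(1, 2), c(0, 1)), "SNP counts")
  expect_error(standardize_effects(c(1, 2, 3), c(1, 2)), "length")
})

test_that("standardize_effects is invariant to affine rescaling at constant SNP count", {
  set.seed(12)
  h2 <- rexp(30); ns <- rep(50, 30)
  expect_equal(standardize_effects(3.2 * h2 + 7, ns),
               standardize_effects(h2, ns))
})

test_that("symmetrize dialects follow their mirror rules", {
  expect_equal(symmetrize(matrix(c(0, 0, 1, 0), 2)), matrix(c(0, 1, 1, 0), 2))
  M <- matrix(c(0, 1, 0, 0), 2)  # lone lower-triangle entry
  expect_equal(symmetrize(M, "upper_to_lower"), matrix(0, 2, 2))
  expect_equal(symmetrize(M, "logical_or"), matrix(c(0, 1, 1, 0), 2))
  S <- matrix(c(1, 2, 2, 1), 2)
  expect_equal(symmetrize(S, "upper_to_lower"), S)
  expect_equal(symmetrize(S, "logical_or"), S)
  expect_error(symmetrize(matrix(0, 2, 3)), "square")
})

test_that("threshold_network applies the cutoff, masks and gene restriction", {
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- 0.3; sc[1, 3] <- 2; sc[2, 3] <- -0.4
  E <- edge_scores(sc, gene_ids = c("a", "b", "c"))
  A0 <- threshold_network(E, tau = 0)
  expect_equal(A0["a", "b"], 1)   # positive score -> edge
  expect_equal(A0["b", "c"], 0)   # negative score -> none
  A5 <- threshold_network(E, tau = 0.5)
  expect_equal(A5["a", "b"], 0)   # 0.3 not > 0.5
  expect_equal(A5["a", "c"], 1)
  # edge-specificity mask excludes the pair at any tau
  es <- matrix(TRUE, 3, 3); es[1, 2] <- FALSE
  Em <- edge_scores(sc, gene_ids = c("a", "b", "c"), edge_specific = es)
  expect_equal(threshold_network(Em, tau = -1)["a", "b"], 0)
  # gene restriction drops non-specific genes
  Eg <- edge_scores(sc, gene_ids = c("a", "b", "c"),
                    gene_specific = c(TRUE, FALSE, TRUE))
  Ag <- threshold_network(Eg)
  expect_equal(rownames(Ag), c("a", "c"))
})

test_that("threshold_network output is always a valid adjacency matrix", {
  set.seed(13)
  for (r in 1:20) {
    m <- sample(3:12, 1)
    E <- edge_scores(matrix(rnorm(m * m), m),
                     edge_specific = matrix(runif(m * m) < 0.7, m),
                     gene_specific = runif(m) < 0.8)
    if (sum(E$gene_specific) < 2) next
    tau <- sample(c(-1, -0.5, 0, 0.5, 1), 1)
    A <- suppressWarnings(threshold_network(E, tau))
    v <- as.vector(as.matrix(A))
    expect_true(all(v %in% c(0, 1)))
    expect_true(Matrix::isSymmetric(A, checkDN = FALSE))
    expect_true(all(Matrix::diag(A) == 0))
  }
})

test_that("distance matrix scales same-chromosome TSS gaps and is 1 across chromosomes", {
  ann <- data.frame(gene_id = c("a", "b", "c", "d"),
                    chromosome = c("1", "1", "1", "2"),
                    tss = c(0, 1e6, 0, 5))
  D <- build_distance_matrix(ann)
  expect_equal(D["a", "b"], 1)   # the maximum same-chromosome gap
  expect_equal(D["a", "c"], 0)   # identical TSS
  expect_equal(D["a", "d"], 1)   # different chromosomes
  expect_equal(diag(D), setNames(rep(0, 4), ann$gene_id))
  expect_true(all(D >= 0 & D <= 1))
  expect_error(build_distance_matrix(ann, gene_ids = c("a", "zz")), "missing annotation")
})

test_that("same-chromosome distance is monotone in the TSS gap", {
  set.seed(14)
  ann <- data.frame(gene_id = paste0("g", 1:10),
                    chromosome = rep(c("1", "2"), each = 5),
                    tss = sample.int(1e7, 10))
  D <- build_distance_matrix(ann)
  gaps <- abs(outer(ann$tss[1:5], ann$tss[1:5], "-"))
  ds <- D[1:5, 1:5]
  ord <- order(gaps[upper.tri(gaps)])
  expect_true(all(diff(ds[upper.tri(ds)][ord]) >= 0))
})

test_that("matrix powers count k-paths with a zeroed diagonal", {
  path3 <- Matrix::Matrix(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3), sparse = TRUE)
  P2 <- matrix_power_zero_diag(path3, 2)
  expect_equal(P2[1, 3], 1)   # only 1-2-3 joins genes 1 and 3
  expect_equal(P2[1, 2], 0)
  expect_true(all(Matrix::diag(P2) == 0))
  tri <- Matrix::Matrix(1, 3, 3, sparse = TRUE); Matrix::diag(tri) <- 0
  T2 <- as.matrix(matrix_power_zero_diag(tri, 2))
  expect_equal(unname(T2), matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  A <- random_adjacency(8)
  expect_equal(as.matrix(matrix_power_zero_diag(A, 0)), diag(8))
  expect_equal(as.matrix(matrix_power_zero_diag(A, 1)), as.matrix(A))
  expect_error(matrix_power_zero_diag(A, -1), "non-negative")
  expect_error(matrix_power_zero_diag(A, 5), "k_max")
})

test_that("second power equals a brute-force 2-path enumeration", {
  set.seed(15)
  for (r in 1:10) {
    A <- random_adjacency(sample(4:20, 1))
    expect_equal(as.matrix(matrix_power_zero_diag(A, 2)), count_two_paths(A),
                 ignore_attr = TRUE)
  }
})

test_that("align_genes intersects and reorders to the effect vector", {
  y <- setNames(rnorm(4), c("a", "b", "c", "d"))
  A <- random_adjacency(3)
  dimnames(A) <- list(c("c", "a", "b"), c("c", "a", "b"))
  al <- suppressMessages(align_genes(y, list(t1 = A)))
  expect_equal(names(al$y), c("a", "b", "c"))
  expect_equal(rownames(al$tissues$t1), c("a", "b", "c"))
  expect_equal(al$dropped, 1)
})
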