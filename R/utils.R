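#' @importFrom Matrix sparseMatrix rowSums diag t triu isSymmetric readMM writeMM
#' @importFrom stats optim rnorm runif rbinom rgamma rmultinom var sd setNames
#' @importFrom utils read.delim write.table combn packageVersion
NULL

# Internal: coerce to a Matrix sparse/dense matrix without copying semantics
# the callers care about; keeps dimnames.
as_dmat <- function(x) {
  if (inherits(x, "Matrix")) x else Matrix::Matrix(x, sparse = FALSE)
}

stop_validation <- function(...) stop(..., call. = FALSE)

check_square <- function(M, what = "matrix") {
  d <- dim(M)
  if (is.null(d) || length(d) != 2L || d[1] != d[2])
    stop_validation(what, " must be a square matrix")
  invisible(d[1])
}

# Validate the binary / symmetric / zero-diagonal adjacency contract.
check_adjacency <- function(A, what = "adjacency matrix") {
  m <- check_square(A, what)
  if (!is_binary(A))
    stop_validation(what, " must be binary (entries 0/1)")
  if (!Matrix::isSymmetric(A, checkDN = FALSE))
    stop_validation(what, " must be symmetric")
  if (any(Matrix::diag(A) != 0))
    stop_validation(what, " must have a zero diagonal (no self-loops)")
  invisible(m)
}

is_binary <- function(M) {
  v <- if (inherits(M, "sparseMatrix")) M@x else as.vector(M)
  length(v) == 0 || all(v == 0 | v == 1)
}

# Number of unordered connected pairs.
edge_count <- function(A) sum(A != 0) / 2

# Upper-triangle (i < j) edge list of a 0/1 matrix, as a 2-column matrix.
edge_list <- function(A) {
  U <- as(Matrix::triu(as_dmat(A) != 0, k = 1L), "TsparseMatrix")
  cbind(i = U@i + 1L, j = U@j + 1L)
}

# Draw `n` unordered non-edges (i < j) of A uniformly without replacement,
# by rejection against the existing edge key set.  Used by the scenario
# perturbations; cheap while the graph is sparse, still correct when not.
sample_nonedges <- function(A, n, m = nrow(A)) {
  if (n <= 0) return(matrix(integer(0), 0, 2))
  el <- edge_list(A)
  n_nonedges <- m * (m - 1) / 2 - nrow(el)
  if (n > 0.1 * n_nonedges) {
    # dense request: enumerate the non-edges once instead of rejecting
    open <- upper.tri(matrix(FALSE, m, m)) & as.matrix(A) == 0
    pick <- which(open)
    if (n < length(pick)) pick <- sample(pick, n)
    j <- (pick - 1L) %/% m + 1L
    return(cbind(pick - (j - 1L) * m, j))
  }
  taken <- el[, 1] * (m + 1) + el[, 2]
  out <- matrix(0L, n, 2)
  got <- 0L
  while (got < n) {
    draw <- 2L * (n - got) + 16L
    i <- sample.int(m, draw, replace = TRUE)
    j <- sample.int(m, draw, replace = TRUE)
    sw <- i > j
    tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
    key <- i * (m + 1) + j
    ok <- i < j & !(key %in% taken) & !duplicated(key)
    i <- i[ok]; j <- j[ok]
    take <- min(length(i), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take), ] <- cbind(i[seq_len(take)], j[seq_len(take)])
      taken <- c(taken, (i * (m + 1) + j)[seq_len(take)])
      got <- got + take
    }
  }
  out
}

# Build a symmetric 0/1 sparse matrix from an i<j edge list.
adjacency_from_edges <- function(edges, m, gene_ids = NULL) {
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(m, m))
  if (!is.null(gene_ids)) dimnames(A) <- list(gene_ids, gene_ids)
  A
}

# Deterministic substream seeds: a small Lehmer-style hash of (seed, index)
# keeps every double exactly representable and the result inside 32-bit
# range, so replicate/subsample streams are reproducible and independent of
# how many of them are drawn.
substream_seed <- function(seed, index) {
  M <- 2147483647
  h <- (((seed %% M) * 48271) %% M + (index * 69621) %% M + 12345) %% M
  as.integer(h)
}
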