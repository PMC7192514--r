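#' Standardize gene-level heritability estimates into an effect vector
#'
#' Scales each gene-level heritability estimate by the number of cis-SNPs
#' assigned to the gene, then standardizes the scaled values across genes to
#' mean zero and standard deviation one (sample standard deviation,
#' denominator `m - 1`).  The result is the outcome vector `y` of the
#' covariance regression network model.
#'
#' @param h2 Numeric vector of per-gene heritability estimates.
#' @param n_snps Integer vector of per-gene SNP counts (all `>= 1`).
#' @param gene_ids Optional character vector of gene identifiers; defaults to
#'   `names(h2)`.
#' @return A named numeric vector `y` with `mean(y) == 0` and `sd(y) == 1`.
#' @examples
#' standardize_effects(c(1, 4, 9), c(1, 2, 3))
#' @export
standardize_effects <- function(h2, n_snps, gene_ids = names(h2)) {
  if (length(h2) != length(n_snps))
    stop_validation("h2 and n_snps must have the same length")
  if (length(h2) < 2)
    stop_validation("at least two genes are required for standardization")
  if (any(!is.finite(n_snps)) || any(n_snps < 1))
    stop_validation("all SNP counts must be >= 1")
  scaled <- h2 / n_snps
  s <- stats::sd(scaled)
  if (!is.finite(s) || s == 0)
    stop_validation("scaled heritability values have zero variance; ",
                    "effects cannot be standardized")
  y <- (scaled - mean(scaled)) / s
  if (!is.null(gene_ids)) names(y) <- gene_ids
  y
}

#' Symmetrize a square matrix
#'
#' Two dialects are supported.  `"upper_to_lower"` copies the upper triangle
#' onto the lower one (the convention of `Matrix::forceSymmetric`), which is
#' the behaviour used when preparing co-expression edge-score matrices.
#' `"logical_or"` takes the elementwise maximum of `M` and `t(M)`, the
#' natural choice for thresholded matrices of an undirected network.
#'
#' @param M A square matrix (base or `Matrix`).
#' @param dialect `"upper_to_lower"` (default) or `"logical_or"`.
#' @return A symmetric matrix of the same dimension.
#' @export
symmetrize <- function(M, dialect = c("upper_to_lower", "logical_or")) {
  dialect <- match.arg(dialect)
  check_square(M, "input to symmetrize")
  if (dialect == "upper_to_lower") {
    as.matrix(Matrix::forceSymmetric(as_dmat(M), uplo = "U"))
  } else {
    as.matrix(pmax(as.matrix(M), t(as.matrix(M))))
  }
}

#' Edge-score container for network thresholding
#'
#' Bundles a continuous gene-gene edge-score matrix (as produced by network
#' inference tools such as PANDA; scores roughly mean zero, unit sd across
#' pairs) with the specificity masks used to restrict to tissue-specific
#' edges and genes.
#'
#' @param scores `m x m` numeric matrix of edge scores; may be asymmetric.
#' @param gene_ids Character vector of `m` unique gene identifiers.
#' @param edge_specific `m x m` logical matrix: edge is specific to at least
#'   one tissue.  Defaults to all `TRUE`.
#' @param gene_specific Length-`m` logical: gene is specific in at least two
#'   tissues or is a retained transcription factor.  Defaults to all `TRUE`.
#' @return An object of class `"edge_scores"`.
#' @export
edge_scores <- function(scores, gene_ids = rownames(scores),
                        edge_specific = NULL, gene_specific = NULL) {
  m <- check_square(scores, "edge-score matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(m))
  if (length(gene_ids) != m) stop_validation("gene_ids length must match matrix size")
  if (anyDuplicated(gene_ids)) stop_validation("gene_ids must be unique")
  if (is.null(edge_specific)) edge_specific <- matrix(TRUE, m, m)
  if (is.null(gene_specific)) gene_specific <- rep(TRUE, m)
  if (!identical(dim(edge_specific), dim(scores)))
    stop_validation("edge_specific must have the same shape as scores")
  if (length(gene_specific) != m)
    stop_validation("gene_specific must have one flag per gene")
  structure(list(scores = as.matrix(scores), gene_ids = as.character(gene_ids),
                 edge_specific = edge_specific, gene_specific = gene_specific),
            class = "edge_scores")
}

#' Hard-threshold continuous edge scores into a binary adjacency matrix
#'
#' Converts an edge to 1 when its (symmetrized) score exceeds `tau` strictly
#' and the edge is flagged tissue-specific; everything else becomes 0.  The
#' gene set is restricted to genes flagged in `gene_specific`, and the
#' diagonal is forced to zero so the network has no self-loops.  `tau = 0`
#' reproduces the "positive edge value" rule; typical sensitivity cutoffs
#' are -1, -0.5, 0, 0.5 and 1.
#'
#' @param E An [edge_scores()] object.
#' @param tau Finite threshold; an edge needs `score > tau`.  Default 0.
#' @param dialect Symmetrization dialect, see [symmetrize()].
#' @return A binary symmetric zero-diagonal adjacency matrix (sparse,
#'   with gene identifiers as dimnames) over the retained genes.
#' @export
threshold_network <- function(E, tau = 0,
                              dialect = c("upper_to_lower", "logical_or")) {
  if (!inherits(E, "edge_scores")) stop_validation("E must be an edge_scores object")
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau))
    stop_validation("tau must be a single finite number")
  dialect <- match.arg(dialect)
  S <- symmetrize(E$scores, dialect)
  mask <- symmetrize(E$edge_specific * 1, dialect) > 0
  a <- (S > tau) & mask
  keep <- which(E$gene_specific)
  a <- a[keep, keep, drop = FALSE]
  diag(a) <- FALSE
  ids <- E$gene_ids[keep]
  A <- methods::as(Matrix::Matrix(a * 1, sparse = TRUE), "generalMatrix")
  dimnames(A) <- list(ids, ids)
  if (edge_count(A) == 0)
    warning("thresholding produced a network with no edges; ",
            "model fits on it will be uninformative", call. = FALSE)
  A
}

#' Scaled TSS distance matrix
#'
#' For genes on the same chromosome the entry is the absolute difference of
#' transcription start sites divided by the maximum same-chromosome distance
#' in the retained gene set; genes on different chromosomes get distance 1;
#' the diagonal is 0.  Used as an optional extra covariance component to
#' control for gene-distance confounding.
#'
#' @param annotation Data frame with columns `gene_id`, `chromosome`, `tss`
#'   (`tss >= 0`), one row per gene.
#' @param gene_ids Optional character vector giving the genes (and order) to
#'   build the matrix for; every id must be annotated.  Defaults to the
#'   annotation order.
#' @return An `m x m` numeric matrix with entries in `[0, 1]`.
#' @export
build_distance_matrix <- function(annotation, gene_ids = NULL) {
  req <- c("gene_id", "chromosome", "tss")
  if (!all(req %in% names(annotation)))
    stop_validation("annotation must have columns gene_id, chromosome, tss")
  if (anyDuplicated(annotation$gene_id))
    stop_validation("annotation has duplicated gene ids")
  if (any(annotation$tss < 0)) stop_validation("tss must be non-negative")
  if (is.null(gene_ids)) gene_ids <- as.character(annotation$gene_id)
  idx <- match(gene_ids, annotation$gene_id)
  if (anyNA(idx))
    stop_validation("missing annotation for gene(s): ",
                    paste(utils::head(gene_ids[is.na(idx)], 5), collapse = ", "))
  chrom <- as.character(annotation$chromosome)[idx]
  tss <- as.numeric(annotation$tss)[idx]
  same <- outer(chrom, chrom, "==")
  d <- abs(outer(tss, tss, "-"))
  dmax <- max(d[same & upper.tri(d)], 0)
  D <- matrix(1, length(idx), length(idx))
  if (dmax > 0) D[same] <- d[same] / dmax else D[same] <- 0
  diag(D) <- 0
  dimnames(D) <- list(gene_ids, gene_ids)
  D
}

#' Zero-diagonal matrix powers of an adjacency matrix
#'
#' `A^(k)` counts the k-paths between gene pairs: its `ij` entry is the
#' number of paths of length `k` linking gene `i` to gene `j`.  The diagonal
#' is forced to zero for `k >= 1` (paths back to the same gene carry no
#' pairwise information), and `k = 0` returns the identity.
#'
#' @param A Binary symmetric zero-diagonal adjacency matrix.
#' @param k Integer power, `0 <= k <= k_max`.
#' @param k_max Largest admissible power (default 4; higher-order path
#'   counts rarely add signal and grow quickly).
#' @return A symmetric integer-valued matrix with zero diagonal (identity
#'   for `k = 0`).
#' @export
matrix_power_zero_diag <- function(A, k, k_max = 4) {
  check_adjacency(A)
  if (length(k) != 1 || k != round(k) || k < 0)
    stop_validation("k must be a single non-negative integer")
  if (k > k_max)
    stop_validation("k = ", k, " exceeds k_max = ", k_max)
  m <- nrow(A)
  if (k == 0) return(Matrix::Diagonal(m))
  P <- as_dmat(A)
  Ak <- P
  if (k > 1) for (step in seq_len(k - 1)) Ak <- Ak %*% P
  Ak <- methods::as(Ak, "generalMatrix")
  Matrix::diag(Ak) <- 0
  Matrix::drop0(Ak)
}

#' Align effect vector, adjacency matrices and distance matrix on shared genes
#'
#' Intersects the gene universes of all inputs, reorders everything to the
#' effect vector's order, and drops (with a message) genes absent from any
#' input.
#'
#' @param y Named numeric effect vector.
#' @param tissues Named list of adjacency matrices with gene-id dimnames.
#' @param distance Optional distance matrix with gene-id dimnames.
#' @return List with elements `y`, `tissues`, `distance`, `dropped` (count).
#' @export
align_genes <- function(y, tissues, distance = NULL) {
  if (is.null(names(y))) stop_validation("y must carry gene ids as names")
  ids <- names(y)
  for (A in tissues) {
    if (is.null(rownames(A))) stop_validation("every adjacency matrix needs gene-id dimnames")
    ids <- intersect(ids, rownames(A))
  }
  if (!is.null(distance)) ids <- intersect(ids, rownames(distance))
  dropped <- length(y) - length(ids)
  if (length(ids) < 2) stop_validation("fewer than 2 genes shared across inputs")
  if (dropped > 0)
    message("align_genes: dropped ", dropped, " gene(s) absent from some input")
  list(y = y[ids],
       tissues = lapply(tissues, function(A) A[ids, ids, drop = FALSE]),
       distance = if (!is.null(distance)) distance[ids, ids, drop = FALSE],
       dropped = dropped)
}
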