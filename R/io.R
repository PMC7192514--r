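# File formats: adjacency matrices travel as Matrix Market coordinate files
# (with a one-id-per-line sidecar *.genes.txt) or dense TSV with gene ids in
# the header row and first column; effect vectors and annotations are TSV.

genes_sidecar <- function(path) sub("\\.mtx$", ".genes.txt", path)

#' Read an adjacency matrix
#'
#' Reads `.mtx` (Matrix Market coordinate; gene ids from `gene_ids` or the
#' `*.genes.txt` sidecar if present) or dense `.tsv` (gene ids as header row
#' and first column).  Non-binary entries are binarized (any nonzero
#' becomes 1) with a warning, a nonzero diagonal is zeroed with a warning,
#' and an asymmetric matrix is symmetrized per `dialect` with a warning.
#'
#' @param path File path ending in `.mtx` or `.tsv`.
#' @param gene_ids Optional path to a gene-id file (one id per line) for
#'   `.mtx` input.
#' @param dialect Symmetrization dialect applied if needed, see
#'   [symmetrize()].
#' @return A validated sparse binary adjacency matrix with gene-id dimnames
#'   (when ids are available).
#' @export
read_adjacency <- function(path, gene_ids = NULL,
                           dialect = c("upper_to_lower", "logical_or")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    M <- methods::as(Matrix::readMM(path), "dMatrix")
    ids <- NULL
    idpath <- if (!is.null(gene_ids)) gene_ids else genes_sidecar(path)
    if (file.exists(idpath)) ids <- readLines(idpath)
  } else {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    M <- as.matrix(df)
    ids <- rownames(df)
  }
  M <- as_dmat(M)
  if (!is.null(ids)) {
    if (length(ids) != nrow(M))
      stop_validation("gene-id count (", length(ids),
                      ") does not match matrix dimension (", nrow(M), ")")
    if (anyDuplicated(ids)) stop_validation("duplicated gene ids in ", path)
  }
  check_square(M, "adjacency matrix")
  vals <- if (inherits(M, "sparseMatrix")) M@x else as.vector(M)
  if (length(vals) && !all(vals %in% c(0, 1))) {
    warning("non-binary entries in ", path, "; binarized (nonzero -> 1)",
            call. = FALSE)
    M <- (M != 0) * 1
  }
  if (any(Matrix::diag(M) != 0)) {
    warning("nonzero diagonal in ", path, "; set to zero", call. = FALSE)
    Matrix::diag(M) <- 0
  }
  if (!Matrix::isSymmetric(M, checkDN = FALSE)) {
    warning("asymmetric matrix in ", path, "; symmetrized (", dialect, ")",
            call. = FALSE)
    M <- symmetrize(as.matrix(M), dialect)
  }
  A <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE), "dMatrix"),
                   "generalMatrix")
  A <- Matrix::drop0(A)
  if (!is.null(ids)) dimnames(A) <- list(ids, ids)
  check_adjacency(A)
  A
}

#' Write an adjacency matrix
#'
#' `.mtx` output writes a Matrix Market coordinate file plus a
#' `*.genes.txt` sidecar when gene ids are present; `.tsv` writes a dense
#' table with ids in header row and first column.
#'
#' @param A Adjacency matrix.
#' @param path Output path ending in `.mtx` or `.tsv`.
#' @export
write_adjacency <- function(A, path) {
  check_adjacency(A)
  ids <- rownames(A)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(methods::as(as_dmat(A), "dMatrix"),
                                "CsparseMatrix"), path)
    if (!is.null(ids)) writeLines(ids, genes_sidecar(path))
  } else {
    M <- as.matrix(A)
    if (is.null(ids)) ids <- paste0("g", seq_len(nrow(M)))
    dimnames(M) <- list(ids, ids)
    utils::write.table(M, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' Read a gene-level effect vector
#'
#' Two-column TSV `gene_id<TAB>value`, header optional (detected by whether
#' the second field of the first line parses as a number).
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop_validation("empty effects file: ", path)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- utils::read.delim(path, header = has_header,
                          col.names = c("gene_id", "value"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0) stop_validation("empty effects file: ", path)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop_validation("duplicated gene id(s) in effects file: ",
                    paste(unique(dup), collapse = ", "))
  if (anyNA(df$value)) stop_validation("non-numeric value(s) in effects file")
  stats::setNames(df$value, df$gene_id)
}

#' Write a gene-level effect vector
#' @param y Named numeric vector.
#' @param path Output TSV path.
#' @export
write_effects <- function(y, path) {
  ids <- names(y)
  if (is.null(ids)) ids <- paste0("g", seq_along(y))
  utils::write.table(data.frame(gene_id = ids,
                                value = format(unname(y), digits = 17,
                                               trim = TRUE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Three-column TSV `gene_id<TAB>chromosome<TAB>tss`, header optional.
#' @param path File path.
#' @return Data frame with columns `gene_id`, `chromosome`, `tss`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][3])))
  df <- utils::read.delim(path, header = has_header,
                          col.names = c("gene_id", "chromosome", "tss"),
                          colClasses = c("character", "character", "numeric"))
  if (anyDuplicated(df$gene_id))
    stop_validation("duplicated gene id(s) in annotation")
  df
}

run_metadata <- function(seed = NULL, command = NULL) {
  c(paste0("# coconet ", as.character(utils::packageVersion("coconet"))),
    if (!is.null(command)) paste0("# command: ", command),
    if (!is.null(seed)) paste0("# seed: ", seed))
}

#' Write a tissue ranking table
#'
#' TSV with columns tissue, loglik, delta_loglik, bic, rank,
#' reproducibility, sorted by rank, preceded by `#` metadata lines (tool
#' version, command, seed).
#'
#' @param ranking A `"coconet_ranking"` object (possibly carrying
#'   reproducibility scores).
#' @param path Output path.
#' @param seed,command Optional metadata echoed into the header.
#' @export
write_ranking <- function(ranking, path, seed = NULL, command = NULL) {
  if (inherits(ranking, "coconet_reproducibility")) ranking <- ranking$ranking
  if (!inherits(ranking, "coconet_ranking"))
    stop_validation("ranking must be a coconet_ranking object")
  tab <- ranking$table[order(ranking$table$rank), ]
  tab$loglik <- format(tab$loglik, digits = 17, trim = TRUE)
  tab$delta_loglik <- format(tab$delta_loglik, digits = 17, trim = TRUE)
  tab$bic <- format(tab$bic, digits = 17, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(run_metadata(seed, command), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a model fit as JSON
#'
#' Serializes parameters, composite log-likelihood, rho, BIC and
#' convergence metadata, with tool version, command line and seed.
#'
#' @param fit A `"coconet"` fit.
#' @param path Output path.
#' @param seed,command Optional metadata.
#' @export
write_fit <- function(fit, path, seed = NULL, command = NULL) {
  if (!inherits(fit, "coconet")) stop_validation("fit must be a coconet object")
  out <- list(version = as.character(utils::packageVersion("coconet")),
              command = command, seed = seed,
              params = list(mu = fit$theta$mu,
                            sigma2 = as.vector(fit$theta$sigma2),
                            sigma2_d = fit$theta$sigma2_d),
              K = fit$K, m = fit$m, n_pairs = fit$n_pairs,
              loglik = fit$loglik, rho = fit$rho, bic = fit$bic,
              converged = fit$converged, n_evals = fit$n_evals)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Generate a small self-consistent demo data set
#'
#' Writes, under `out_dir`: an effect vector simulated at `rho = 0.05`
#' from tissue 1 of five block-diagonal tissue networks of 200 genes
#' (`tissue_1.mtx` ... `tissue_5.mtx` with gene-id sidecars), a gene
#' annotation table, and a `manifest.json` recording the seed and the
#' generating tissue.  Deterministic given `seed`; intended to exercise
#' every command end-to-end in seconds.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Seed (default 1).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  m <- 200; n_tissues <- 5; rho <- 0.05
  ids <- sprintf("gene%03d", seq_len(m))
  As <- replicate(n_tissues,
                  generate_block_adjacency(m, cluster_range = 10:15),
                  simplify = FALSE)
  As <- lapply(As, function(A) { dimnames(A) <- list(ids, ids); A })
  y <- simulate_outcome(As[[1]], rho)
  names(y) <- ids
  for (t in seq_len(n_tissues))
    write_adjacency(As[[t]], file.path(out_dir, sprintf("tissue_%d.mtx", t)))
  write_effects(y, file.path(out_dir, "effects.tsv"))
  ann <- data.frame(gene_id = ids,
                    chromosome = paste0("chr", sample(1:5, m, replace = TRUE)),
                    tss = sample.int(2e8, m))
  utils::write.table(ann, file.path(out_dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(version = as.character(utils::packageVersion("coconet")),
                   seed = seed, m = m, n_tissues = n_tissues, rho = rho,
                   true_tissue = 1)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
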