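#' Bivariate-normal log-density of one centered gene pair
#'
#' Log-density of `(z_i, z_j)` under a bivariate normal with zero mean,
#' common variance `v` and covariance `c`:
#' `-log(2*pi) - log(v^2 - c^2)/2 - (v*(z_i^2 + z_j^2) - 2*c*z_i*z_j) / (2*(v^2 - c^2))`.
#' In the model `v` is the residual variance and `c` is the network-implied
#' covariance of the pair.  Vectorized over all arguments; pairs with an
#' invalid covariance (`abs(c) >= v`) evaluate to `-Inf`, which the fitter
#' treats as a penalty.
#'
#' @param z_i,z_j Centered effect values of the two genes.
#' @param v Common variance (`> 0`).
#' @param c_ij Covariance implied by the network for the pair.
#' @return Log-density value(s); `-Inf` where `abs(c_ij) >= v`.
#' @export
pair_loglik <- function(z_i, z_j, v, c_ij) {
  if (any(v <= 0)) stop_validation("variance v must be positive")
  det <- v^2 - c_ij^2
  ll <- -log(2 * pi) - 0.5 * log(det) -
    (v * (z_i^2 + z_j^2) - 2 * c_ij * z_i * z_j) / (2 * det)
  ll[abs(c_ij) >= v] <- -Inf
  ll
}

#' Group gene pairs by covariance pattern with sufficient statistics
#'
#' The composite likelihood sums a bivariate-normal log-density over all
#' `m(m-1)/2` unordered gene pairs, but the density of a pair depends on the
#' data only through its covariance pattern `(a_ij^(1), ..., a_ij^(K))` (and
#' optionally a distance value).  Grouping pairs by pattern and keeping
#' `n_pairs`, `S1 = sum(y_i + y_j)`, `S2 = sum(y_i^2 + y_j^2)` and
#' `S12 = sum(y_i * y_j)` per group makes each likelihood evaluation cost
#' proportional to the number of distinct patterns rather than to `m^2`,
#' which is what keeps fitting fast at thousands of genes.
#'
#' For the common case `K = 1` without a distance component only two
#' patterns exist (connected / unconnected pair) and the statistics are
#' assembled from degree sums and one sparse quadratic form without ever
#' enumerating pairs.
#'
#' @param y Numeric effect vector.
#' @param powers A single adjacency matrix, or a list of zero-diagonal
#'   matrix powers `A^(k)` for `k = 1..K` (see [matrix_power_zero_diag()]).
#' @param d Optional distance matrix aligned with `y`.
#' @param d_bins Number of equal-width bins over `[0, 1]` used to discretize
#'   distances in `"bin"` mode (default 64); each group's representative
#'   distance is the mean distance of its pairs.
#' @param d_mode `"bin"` (default) or `"exact"`; exact mode keys groups on
#'   the distinct distance values so the grouped likelihood reproduces the
#'   naive pairwise sum to machine precision at `O(m^2)` group cost.
#' @return An object of class `"pair_groups"`.
#' @export
build_pair_groups <- function(y, powers, d = NULL, d_bins = 64,
                              d_mode = c("bin", "exact")) {
  d_mode <- match.arg(d_mode)
  if (!is.list(powers)) powers <- list(powers)
  K <- length(powers)
  if (K < 1) stop_validation("at least one adjacency power is required")
  m <- length(y)
  for (P in powers)
    if (!all(dim(P) == m)) stop_validation("matrix dimensions must match length(y)")
  if (!is.null(d) && !all(dim(d) == m))
    stop_validation("distance matrix dimensions must match length(y)")

  if (K == 1 && is.null(d) && is_binary(powers[[1]])) {
    g <- fast_groups_k1(y, powers[[1]])
  } else {
    g <- generic_groups(y, powers, d, d_bins, d_mode)
  }
  g$m <- m
  g$K <- K
  g$has_distance <- !is.null(d)
  class(g) <- "pair_groups"
  g
}

# Internal constructor for trusted binary input (skips the binary scan,
# which costs a full pass over dense storage).
pair_groups_k1 <- function(y, A) {
  g <- fast_groups_k1(y, A)
  g$m <- length(y)
  g$K <- 1L
  g$has_distance <- FALSE
  class(g) <- "pair_groups"
  g
}

# Two-pattern grouping for K = 1 binary adjacency: totals over all pairs via
# vector identities, totals over connected pairs via degree sums and y'Ay.
fast_groups_k1 <- function(y, A) {
  m <- length(y)
  deg <- Matrix::rowSums(A)
  n_e <- sum(deg) / 2
  S1_e <- sum(deg * y)
  S2_e <- sum(deg * y^2)
  S12_e <- as.numeric(y %*% (A %*% y)) / 2
  n_all <- m * (m - 1) / 2
  sy <- sum(y); sy2 <- sum(y^2)
  S1_all <- (m - 1) * sy
  S2_all <- (m - 1) * sy2
  S12_all <- (sy^2 - sy2) / 2
  if (n_e == 0) {
    list(patterns = matrix(0, 1, 1), d_values = NULL,
         n_pairs = n_all, S1 = S1_all, S2 = S2_all, S12 = S12_all)
  } else {
    list(patterns = matrix(c(0, 1), 2, 1), d_values = NULL,
         n_pairs = c(n_all - n_e, n_e),
         S1 = c(S1_all - S1_e, S1_e),
         S2 = c(S2_all - S2_e, S2_e),
         S12 = c(S12_all - S12_e, S12_e))
  }
}

# General grouping: enumerate the upper triangle once, build a compound key
# across the K path-count values (and the distance bin), and reduce with
# rowsum().  Memory is O(m^2) doubles, fine into the low thousands of genes.
generic_groups <- function(y, powers, d, d_bins, d_mode) {
  m <- length(y)
  ut <- upper.tri(matrix(0, m, m))
  cols <- lapply(powers, function(P) as.matrix(P)[ut])
  dval <- NULL
  if (!is.null(d)) {
    dv <- as.matrix(d)[ut]
    if (d_mode == "exact") {
      cols <- c(cols, list(match(dv, sort(unique(dv))) - 1))
      dval <- dv
    } else {
      bin <- pmin(floor(dv * d_bins), d_bins - 1)
      cols <- c(cols, list(bin))
      dval <- dv
    }
  }
  key <- cols[[1]]
  if (length(cols) > 1) {
    overflow <- FALSE
    radix <- 1
    for (k in seq_along(cols)) {
      mx <- max(cols[[k]]) + 1
      radix <- radix * mx
      if (radix > 2^52) { overflow <- TRUE; break }
    }
    if (overflow) {
      key <- do.call(paste, c(cols, sep = "\r"))
    } else {
      key <- cols[[1]]
      for (k in seq_along(cols)[-1]) key <- key * (max(cols[[k]]) + 1) + cols[[k]]
    }
  }
  f <- match(key, unique(key))
  idx <- which(ut, arr.ind = TRUE)
  yi <- y[idx[, 1]]; yj <- y[idx[, 2]]
  agg <- rowsum(cbind(1, yi + yj, yi^2 + yj^2, yi * yj,
                      if (!is.null(dval)) dval),
                f, reorder = TRUE)
  first <- which(!duplicated(f))
  ord <- f[first]
  pat <- do.call(cbind, lapply(seq_along(powers), function(k) cols[[k]][first]))
  pat <- pat[order(ord), , drop = FALSE]
  list(patterns = pat,
       d_values = if (!is.null(dval)) agg[, 5] / agg[, 1],
       n_pairs = agg[, 1], S1 = agg[, 2], S2 = agg[, 3], S12 = agg[, 4])
}

#' @export
print.pair_groups <- function(x, ...) {
  cat("Pair groups: m =", x$m, "genes,", length(x$n_pairs),
      "covariance pattern(s), K =", x$K,
      if (x$has_distance) "(with distance component)", "\n")
  invisible(x)
}

#' Composite log-likelihood from grouped sufficient statistics
#'
#' Evaluates the pairwise composite log-likelihood
#' `sum over pairs i < j of log P(y_i, y_j | theta)` using the grouped
#' representation from [build_pair_groups()]; the result is algebraically
#' identical to summing [pair_loglik()] over all pairs (exactly so in
#' exact-distance mode, to binning resolution otherwise).
#'
#' @param theta List with elements `mu` (intercept), `sigma2` (numeric
#'   vector `c(sigma0^2, sigma1^2, ..., sigmaK^2)`, `sigma0^2 > 0`, the rest
#'   `>= 0`) and optionally `sigma2_d` (distance-component coefficient).
#' @param groups A `"pair_groups"` object.
#' @return The composite log-likelihood; `-Inf` if any observed pattern
#'   implies a non-positive-definite pair covariance (`abs(c) >= sigma0^2`).
#' @export
composite_loglik <- function(theta, groups) {
  if (!inherits(groups, "pair_groups")) stop_validation("groups must be a pair_groups object")
  sig <- theta$sigma2
  if (length(sig) != groups$K + 1)
    stop_validation("theta$sigma2 must have length K + 1 = ", groups$K + 1)
  if (sig[1] <= 0) stop_validation("sigma0^2 must be positive")
  if (any(sig < 0)) stop_validation("variance components must be non-negative")
  v <- sig[1]
  cvec <- as.vector(groups$patterns %*% sig[-1])
  if (groups$has_distance) {
    if (is.null(theta$sigma2_d)) stop_validation("theta$sigma2_d required for distance groups")
    cvec <- cvec + theta$sigma2_d * groups$d_values
  }
  if (any(abs(cvec) >= v)) return(-Inf)
  mu <- theta$mu
  n <- groups$n_pairs
  Z2 <- groups$S2 - 2 * mu * groups$S1 + 2 * n * mu^2
  Z12 <- groups$S12 - mu * groups$S1 + n * mu^2
  det <- v^2 - cvec^2
  sum(n * (-log(2 * pi) - 0.5 * log(det)) - (v * Z2 - 2 * cvec * Z12) / (2 * det))
}
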