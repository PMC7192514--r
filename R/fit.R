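#' Fit the covariance regression network model by composite likelihood
#'
#' Models a gene-level effect vector `y` as multivariate normal with mean
#' `mu` and covariance `sigma0^2 I + sigma1^2 A + ... + sigmaK^2 A^(K)`
#' (plus an optional `sigma_d^2 D` distance component), where `A` is a
#' tissue's binary gene co-expression adjacency matrix and `A^(k)` counts
#' k-paths between genes.  Parameters are estimated by maximising the
#' pairwise composite log-likelihood (the sum of bivariate-normal
#' log-densities over all gene pairs) with Nelder-Mead simplex search;
#' variances are optimised on the log scale so positivity needs no explicit
#' constraint, and parameter values implying a non-positive-definite pair
#' covariance are rejected with a large penalty.
#'
#' The derived signal strength `rho = sigma1^2 / (sigma0^2 + sigma1^2)`
#' measures the share of pairwise covariance attributable to direct network
#' connections; the maximised composite likelihood is the quantity used to
#' rank candidate tissues.
#'
#' @param y Numeric effect vector (typically standardized, see
#'   [standardize_effects()]); gene ids may be supplied as names.
#' @param A Binary symmetric zero-diagonal adjacency matrix (base matrix or
#'   `Matrix` sparse matrix).  If both `y` and `A` carry gene ids they must
#'   agree in order (use [align_genes()] beforehand otherwise).
#' @param K Polynomial order of the covariance, between 1 and 4.  `K = 1`
#'   (direct connections only) is the default and is generally preferred by
#'   BIC.
#' @param distance Optional distance matrix (see [build_distance_matrix()])
#'   entering the covariance as an extra component `sigma_d^2 D`.
#' @param control List of fitting options: `maxit` (default 2000), `reltol`
#'   (relative convergence tolerance, default 1e-8), `n_starts` (Nelder-Mead
#'   restarts from jittered initial values, default 1), `seed` (seed for the
#'   restart jitter), `d_bins` and `d_mode` (distance grouping, see
#'   [build_pair_groups()]), and `validate` (set `FALSE` to skip the
#'   adjacency-contract checks when the matrix is known valid, e.g. inside
#'   simulation loops).
#' @return An object of class `"coconet"` with components `coefficients`
#'   (`mu`, `sigma2` vector, optional `sigma2_d`), `rho`, `loglik`, `bic`,
#'   `converged`, `n_evals`, plus the data and pair groups used.
#' @seealso [coconet_rank()] to fit many tissues and rank them,
#'   [run_power_experiment()] for the simulation study.
#' @examples
#' set.seed(1)
#' A <- generate_block_adjacency(120, cluster_range = 4:6)
#' y <- simulate_outcome(A, rho = 0.1)
#' fit <- coconet(y, A)
#' fit
#' coef(fit)
#' @export
coconet <- function(y, A, K = 1, distance = NULL, control = list()) {
  cl <- match.call()
  ctrl <- modifyList(list(maxit = 2000, reltol = 1e-8, n_starts = 1,
                          seed = NULL, d_bins = 64, d_mode = "bin",
                          validate = TRUE),
                     control)
  if (!is.numeric(y) || length(y) < 2) stop_validation("y must be a numeric vector, length >= 2")
  m <- if (ctrl$validate) check_adjacency(A) else nrow(A)
  if (m != length(y)) stop_validation("dim(A) must match length(y)")
  if (!is.null(names(y)) && !is.null(rownames(A)) &&
      !identical(names(y), rownames(A)))
    stop_validation("gene ids of y and A disagree; align inputs first (align_genes)")
  if (length(K) != 1 || K != round(K) || K < 1 || K > 4)
    stop_validation("K must be an integer between 1 and 4")
  if (!is.null(distance)) {
    check_square(distance, "distance matrix")
    if (nrow(distance) != m) stop_validation("distance matrix must match length(y)")
  }

  if (edge_count(A) == 0) {
    warning("adjacency matrix has no edges; network variance components ",
            "are unidentifiable and reported as 0", call. = FALSE)
    return(empty_network_fit(y, A, K, cl))
  }

  groups <- if (K == 1 && is.null(distance)) {
    pair_groups_k1(y, A)
  } else {
    powers <- lapply(seq_len(K), function(k)
      matrix_power_zero_diag(A, k, k_max = max(4, K)))
    build_pair_groups(y, powers, d = distance,
                      d_bins = ctrl$d_bins, d_mode = ctrl$d_mode)
  }

  has_d <- !is.null(distance)
  npar <- 2 + K + has_d
  vy <- stats::var(y)
  p0 <- c(mean(y), log(vy), rep(log(0.1 * vy / K), K),
          if (has_d) log(0.1 * vy))

  obj <- function(par) {
    th <- par_to_theta(par, K, has_d)
    ll <- composite_loglik(th, groups)
    if (!is.finite(ll)) -1e10 else ll
  }

  starts <- list(p0)
  if (ctrl$n_starts > 1) {
    jit <- with_local_seed(ctrl$seed, {
      lapply(seq_len(ctrl$n_starts - 1), function(s)
        p0 + c(0, stats::rnorm(npar - 1, sd = 1)))
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = ctrl$maxit,
                                     reltol = ctrl$reltol))
    if (is.null(best) || o$value > best$value) best <- o
  }

  theta <- par_to_theta(best$par, K, has_d)
  rho <- theta$sigma2[2] / (theta$sigma2[1] + theta$sigma2[2])
  n_pairs <- m * (m - 1) / 2
  loglik <- best$value
  fit <- structure(list(
    coefficients = c(mu = theta$mu,
                     stats::setNames(theta$sigma2, paste0("sigma", 0:K, "_sq")),
                     if (has_d) c(sigmaD_sq = theta$sigma2_d)),
    theta = theta, rho = rho, loglik = loglik,
    bic = -2 * loglik + npar * log(n_pairs),
    K = K, m = m, n_pairs = n_pairs, n_params = npar,
    converged = best$convergence == 0, n_evals = best$counts[["function"]],
    has_distance = has_d, y = y, A = A, distance = distance,
    groups = groups, control = ctrl, call = cl), class = "coconet")
  fit
}

par_to_theta <- function(par, K, has_d) {
  list(mu = par[1], sigma2 = exp(par[2:(K + 2)]),
       sigma2_d = if (has_d) exp(par[K + 3]))
}

# Closed-form composite-likelihood maximiser when A has no edges: all pairs
# are independent, so the composite likelihood factorises into (m-1) copies
# of the univariate normal likelihood with MLEs mean(y) and the population
# variance.
empty_network_fit <- function(y, A, K, cl) {
  m <- length(y)
  mu <- mean(y)
  s0 <- mean((y - mu)^2)
  theta <- list(mu = mu, sigma2 = c(s0, rep(0, K)), sigma2_d = NULL)
  n_pairs <- m * (m - 1) / 2
  ll <- (m - 1) * sum(stats::dnorm(y, mu, sqrt(s0), log = TRUE))
  npar <- 2 + K
  structure(list(
    coefficients = c(mu = mu, stats::setNames(theta$sigma2,
                                              paste0("sigma", 0:K, "_sq"))),
    theta = theta, rho = 0, loglik = ll,
    bic = -2 * ll + npar * log(n_pairs),
    K = K, m = m, n_pairs = n_pairs, n_params = npar,
    converged = TRUE, n_evals = 0L, has_distance = FALSE,
    y = y, A = A, distance = NULL, groups = NULL,
    control = list(), call = cl), class = "coconet")
}

# Run expr under a temporary RNG state when seed is non-NULL.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.coconet <- function(x, digits = 4, ...) {
  cat("Composite-likelihood covariance regression network model (K =",
      x$K, ")\n")
  cat("  genes:", x$m, "  pairs:", format(x$n_pairs, big.mark = ","),
      "  edges:", format(edge_count(x$A), big.mark = ","), "\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  cat("  rho =", signif(x$rho, digits),
      "  logLik =", format(x$loglik, digits = 10),
      "  BIC =", format(x$bic, digits = 10), "\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.coconet <- function(object, ...) {
  structure(list(fit = object), class = "summary.coconet")
}

#' @export
print.summary.coconet <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nSignal share rho = sigma1^2/(sigma0^2 + sigma1^2) =",
      signif(f$rho, 4), "\n")
  cat("Converged:", f$converged, " (", f$n_evals,
      "composite-likelihood evaluations )\n")
  invisible(x)
}

#' @export
coef.coconet <- function(object, ...) object$coefficients

#' Composite log-likelihood of a fitted model
#'
#' Note this is a composite (pairwise pseudo-) likelihood, not a joint
#' likelihood; it is directly comparable across tissues at fixed `K` and
#' `m`.  `nobs` is the number of gene pairs, so `stats::BIC()` on this
#' object reproduces the pairs-convention BIC.
#' @param object A `"coconet"` fit.
#' @param ... Unused.
#' @export
logLik.coconet <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_pairs,
            class = "logLik")
}

#' Bayesian Information Criterion for a composite-likelihood fit
#'
#' `BIC = -2 loglik + n_params log(N)` where the observation count `N` is
#' the number of gene pairs (`"pairs"`, default, matching the composite
#' likelihood's summation) or the number of genes (`"genes"`).  Tissue
#' ordering at fixed `K` and `m` is the same under either convention, and
#' identical to ordering by likelihood.
#'
#' @param object A `"coconet"` fit.
#' @param ... Unused.
#' @param convention `"pairs"` or `"genes"`.
#' @export
BIC.coconet <- function(object, ..., convention = c("pairs", "genes")) {
  convention <- match.arg(convention)
  N <- if (convention == "pairs") object$n_pairs else object$m
  -2 * object$loglik + object$n_params * log(N)
}

#' @export
fitted.coconet <- function(object, ...) {
  stats::setNames(rep(object$theta$mu, object$m), names(object$y))
}

#' @export
residuals.coconet <- function(object, ...) object$y - object$theta$mu

#' Simulate effect vectors from a fitted model
#'
#' Draws from `MVN(mu, sum_k sigma_k^2 A^(k) [+ sigma_d^2 D])` at the
#' fitted parameter values.
#' @param object A `"coconet"` fit.
#' @param nsim Number of draws.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A matrix with `nsim` columns, one simulated effect vector each.
#' @export
simulate.coconet <- function(object, nsim = 1, seed = NULL, ...) {
  with_local_seed(seed, {
    th <- object$theta
    Sigma <- Matrix::Diagonal(object$m, th$sigma2[1])
    for (k in seq_len(object$K))
      if (th$sigma2[k + 1] > 0)
        Sigma <- Sigma + th$sigma2[k + 1] *
          matrix_power_zero_diag(object$A, k, k_max = max(4, object$K))
    if (object$has_distance && !is.null(th$sigma2_d))
      Sigma <- Sigma + th$sigma2_d * as_dmat(object$distance)
    R <- chol(as.matrix(Sigma))
    Z <- matrix(stats::rnorm(object$m * nsim), object$m, nsim)
    out <- th$mu + crossprod(R, Z)
    rownames(out) <- names(object$y)
    out
  })
}

#' Profile of the composite log-likelihood over the signal strength
#'
#' Plots `l(rho)` with the intercept and total variance held at their
#' estimates, marking the maximum composite-likelihood estimate.
#' @param x A `"coconet"` fit (with `K = 1`).
#' @param rho_max Upper end of the profiled grid.
#' @param n Grid size.
#' @param ... Passed to `plot`.
#' @export
plot.coconet <- function(x, rho_max = 0.4, n = 81, ...) {
  if (is.null(x$groups)) stop_validation("fit carries no pair groups to profile")
  tot <- x$theta$sigma2[1] + x$theta$sigma2[2]
  grid <- seq(0, rho_max, length.out = n)
  ll <- vapply(grid, function(r) {
    th <- list(mu = x$theta$mu,
               sigma2 = c((1 - r) * tot, r * tot, x$theta$sigma2[-(1:2)]),
               sigma2_d = x$theta$sigma2_d)
    composite_loglik(th, x$groups)
  }, numeric(1))
  ok <- is.finite(ll)
  plot(grid[ok], ll[ok], type = "l", xlab = expression(rho),
       ylab = "composite log-likelihood", ...)
  graphics::abline(v = x$rho, lty = 2)
  invisible(data.frame(rho = grid, loglik = ll))
}
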