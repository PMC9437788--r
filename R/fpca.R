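#' Pointwise mean function of smoothed trajectories
#'
#' @param smoothed Numeric matrix (participants x grid points).
#' @return Numeric vector of column means.
#' @export
estimate_mean <- function(smoothed) {
  if (!is.matrix(smoothed)) stop("'smoothed' must be a matrix")
  if (nrow(smoothed) < 2) stop("need at least 2 participants to estimate a mean function")
  colMeans(smoothed)
}

#' Quadrature weights on a grid
#'
#' @param grid Strictly increasing numeric grid.
#' @param rule `"trapezoid"` (default) or `"rectangle"` (unit weight per
#'   point times the grid spacing).
#' @return Numeric weight vector; `sum(w * f)` approximates the integral of
#'   `f` over the grid.
#' @export
quadrature_weights <- function(grid, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  p <- length(grid)
  if (p < 2) stop("grid must have at least 2 points")
  h <- diff(grid)
  if (rule == "rectangle") {
    return(rep(mean(h), p))
  }
  w <- numeric(p)
  w[1] <- h[1] / 2
  w[p] <- h[p - 1] / 2
  if (p > 2) w[2:(p - 1)] <- (h[-1] + h[-(p - 1)]) / 2
  w
}

# Local-linear smoother matrix with a Gaussian kernel: row i holds the
# weights producing the fit at grid[i] from values at all grid points.
# Rows reproduce constants (sum to 1). Where the local-linear denominator
# degenerates (e.g. bandwidth -> 0, where the kernel mass collapses onto a
# single point), falls back to Nadaraya-Watson weights, so the bandwidth -> 0
# limit of the smoother is the identity.
local_linear_matrix <- function(grid, bandwidth) {
  if (bandwidth <= 0) stop("'bandwidth' must be > 0")
  D <- outer(grid, grid, function(x0, x) x - x0)
  K <- exp(-0.5 * (D / bandwidth)^2)
  s0 <- rowSums(K)
  s1 <- rowSums(K * D)
  s2 <- rowSums(K * D^2)
  den <- s0 * s2 - s1^2
  W <- K * (s2 - D * s1) / den
  bad <- !is.finite(den) | abs(den) < 1e-300
  if (any(bad)) {
    W[bad, ] <- K[bad, , drop = FALSE] / s0[bad]
  }
  W
}

#' Smoothed covariance surface of functional data
#'
#' Computes the raw sample covariance
#' `G(s, t) = sum_i (X_i(s) - mu(s)) (X_i(t) - mu(t)) / (n - 1)`, smooths it
#' with a product-Gaussian local-linear smoother applied along both axes
#' (smoother matrix `L`: output is `L G t(L)`), symmetrizes, and projects
#' onto the positive semidefinite cone by truncating negative eigenvalues
#' at zero.
#'
#' @param smoothed Numeric matrix (n x p) of presmoothed trajectories.
#' @param mean Mean function; defaults to [estimate_mean()].
#' @param bandwidth Gaussian kernel bandwidth in grid units; default 7
#'   (the natural weekly scale of daily engagement data). Very small values
#'   approach no smoothing.
#' @param grid Evaluation grid; default `0:(p-1)` (days).
#' @param exclude_diagonal If `TRUE`, the raw diagonal is replaced by the
#'   average of its adjacent off-diagonal neighbours before smoothing
#'   (sensitivity option for measurement-error-inflated diagonals);
#'   default `FALSE`, since daily noise is already absorbed by the 7-day
#'   presmoothing.
#' @return p x p symmetric positive-semidefinite matrix.
#' @export
estimate_smoothed_covariance <- function(smoothed, mean = NULL, bandwidth = 7,
                                         grid = NULL,
                                         exclude_diagonal = FALSE) {
  if (!is.matrix(smoothed)) stop("'smoothed' must be a matrix")
  if (bandwidth <= 0) stop("'bandwidth' must be > 0")
  n <- nrow(smoothed)
  p <- ncol(smoothed)
  if (is.null(grid)) grid <- seq_len(p) - 1
  if (is.null(mean)) mean <- estimate_mean(smoothed)
  xc <- sweep(smoothed, 2, mean)
  G <- crossprod(xc) / (n - 1)
  if (exclude_diagonal && p >= 3) {
    d <- seq_len(p)
    lo <- pmax(d - 1, 1)
    hi <- pmin(d + 1, p)
    G[cbind(d, d)] <- (G[cbind(d, lo)] + G[cbind(d, hi)]) / 2
  }
  L <- local_linear_matrix(grid, bandwidth)
  Gs <- L %*% G %*% t(L)
  Gs <- (Gs + t(Gs)) / 2
  e <- eigen(Gs, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  Gs <- e$vectors %*% (pos * t(e$vectors))
  (Gs + t(Gs)) / 2
}

#' Eigendecomposition of a covariance surface under quadrature
#'
#' Solves the integral eigenproblem `int G(s, t) phi(t) dt = lambda phi(s)`
#' on the grid via the weighted matrix eigenproblem
#' `W^(1/2) G W^(1/2) v = lambda v`, `phi = v / sqrt(w)`. Eigenfunctions are
#' orthonormal under the quadrature inner product
#' `<f, g> = sum(w * f * g)`; the sign convention makes each
#' eigenfunction's largest-magnitude element positive. Eigenvalues below
#' zero (numerical noise) are clipped to 0.
#'
#' @param cov Symmetric p x p covariance matrix.
#' @param weights Quadrature weights from [quadrature_weights()].
#' @return List with `values` (nonincreasing, >= 0) and `functions`
#'   (p x p matrix, one eigenfunction per column).
#' @export
eigendecompose <- function(cov, weights) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov)) stop("'cov' must be square")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("'cov' must be symmetric")
  }
  p <- nrow(cov)
  stopifnot(length(weights) == p, all(weights > 0))
  sw <- sqrt(weights)
  M <- cov * tcrossprod(sw)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  values <- pmax(e$values, 0)
  fns <- e$vectors / sw
  for (k in seq_len(p)) {
    j <- which.max(abs(fns[, k]))
    if (fns[j, k] < 0) fns[, k] <- -fns[, k]
  }
  list(values = values, functions = fns)
}

#' Project curves onto eigenfunctions
#'
#' Numerical-integration scores for dense, complete curves:
#' `score[i, k] = sum_t w_t (X_i(t) - mu(t)) phi_k(t)`.
#'
#' @param smoothed n x p matrix of curves.
#' @param mean Mean function (length p).
#' @param eigenfunctions p x K matrix, one eigenfunction per column.
#' @param weights Quadrature weights (length p).
#' @return n x K score matrix.
#' @export
compute_scores <- function(smoothed, mean, eigenfunctions, weights) {
  if (!is.matrix(smoothed)) stop("'smoothed' must be a matrix")
  p <- ncol(smoothed)
  if (length(mean) != p || nrow(eigenfunctions) != p || length(weights) != p) {
    stop("dimension mismatch between curves (", p, " points), mean (",
         length(mean), "), eigenfunctions (", nrow(eigenfunctions),
         ") and weights (", length(weights), ")")
  }
  sweep(smoothed, 2, mean) %*% (weights * eigenfunctions)
}

#' Number of components at a variance-explained threshold
#'
#' @param eigenvalues Nonincreasing, nonnegative eigenvalues.
#' @param threshold Minimum cumulative share of total variance; default 0.90.
#' @return Smallest K with `sum(lambda[1:K]) / sum(lambda) >= threshold`.
#' @export
select_num_components <- function(eigenvalues, threshold = 0.90) {
  stopifnot(length(eigenvalues) >= 1, threshold > 0, threshold <= 1)
  if (any(diff(eigenvalues) > 1e-12)) stop("'eigenvalues' must be nonincreasing")
  if (any(eigenvalues < 0)) stop("'eigenvalues' must be nonnegative")
  tot <- sum(eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero: no variance to explain")
  cum <- cumsum(eigenvalues) / tot
  # guard against 0.899999... just below threshold from accumulated rounding
  which(cum >= threshold - 1e-12)[1]
}

#' Functional principal component analysis by smoothed covariance
#'
#' Full FPCA of dense presmoothed trajectories: mean estimation, smoothed
#' covariance surface, quadrature eigendecomposition, component selection at
#' a variance-explained threshold, and projection scores.
#'
#' @param smoothed n x p matrix of presmoothed trajectories (n >= 2).
#' @param threshold Variance-explained threshold for the number of retained
#'   components; default 0.90.
#' @param bandwidth Covariance smoother bandwidth (days); default 7.
#' @param quadrature `"trapezoid"` (default) or `"rectangle"`.
#' @param grid Evaluation grid; default days `0:(p-1)`.
#' @param exclude_diagonal See [estimate_smoothed_covariance()].
#' @return An object of class `fpc_model`: grid, mean, eigenvalues (full
#'   spectrum), eigenfunctions and scores for the K retained components,
#'   per-component variance shares, and the settings used.
#' @export
fit_fpca <- function(smoothed, threshold = 0.90, bandwidth = 7,
                     quadrature = c("trapezoid", "rectangle"), grid = NULL,
                     exclude_diagonal = FALSE) {
  quadrature <- match.arg(quadrature)
  if (!is.matrix(smoothed)) stop("'smoothed' must be a matrix")
  p <- ncol(smoothed)
  if (is.null(grid)) grid <- seq_len(p) - 1
  mu <- estimate_mean(smoothed)
  G <- estimate_smoothed_covariance(smoothed, mu, bandwidth, grid,
                                    exclude_diagonal)
  w <- quadrature_weights(grid, quadrature)
  eg <- eigendecompose(G, w)
  if (sum(eg$values) <= 1e-12 * p) {
    stop("degenerate input: trajectories carry no variance")
  }
  K <- select_num_components(eg$values, threshold)
  phi <- eg$functions[, seq_len(K), drop = FALSE]
  scores <- compute_scores(smoothed, mu, phi, w)
  colnames(scores) <- paste0("FPC", seq_len(K))
  structure(
    list(
      grid = grid, mean = mu,
      eigenvalues = eg$values,
      eigenfunctions = phi,
      scores = scores,
      pct_variance = eg$values[seq_len(K)] / sum(eg$values),
      n_components = K,
      threshold = threshold, bandwidth = bandwidth,
      quadrature = quadrature, weights = w,
      n = nrow(smoothed)
    ),
    class = "fpc_model"
  )
}

#' @export
print.fpc_model <- function(x, ...) {
  cat("FPCA of", x$n, "trajectories on", length(x$grid), "grid points\n")
  cat("Retained", x$n_components, "component(s) at",
      sprintf("%.0f%%", 100 * x$threshold), "variance threshold;",
      "explained:", paste(sprintf("%.1f%%", 100 * x$pct_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize an FPC model to a CSV bundle
#'
#' Writes `mean.csv` (grid, mean), `eigen.csv` (grid, one column per
#' retained eigenfunction), `eigenvalues.csv` and `scores.csv` to `dir`.
#'
#' @param model An `fpc_model`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_fpca <- function(model, dir) {
  stopifnot(inherits(model, "fpc_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(grid = model$grid, mean = model$mean),
                   file.path(dir, "mean.csv"), row.names = FALSE)
  ef <- data.frame(grid = model$grid, model$eigenfunctions)
  names(ef) <- c("grid", paste0("phi", seq_len(model$n_components)))
  utils::write.csv(ef, file.path(dir, "eigen.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(model$eigenvalues),
                              eigenvalue = model$eigenvalues),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$scores),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  invisible(dir)
}
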