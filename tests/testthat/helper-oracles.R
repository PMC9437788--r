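# Independent oracles and small generators used across test files.

# Exhaustive k-medoids optimum: scan all medoid subsets of size k.
brute_force_kmedoids <- function(points, k) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  D <- as.matrix(dist(points))
  n <- nrow(D)
  best <- Inf
  for (med in asplit(utils::combn(n, k), 2)) {
    cost <- sum(do.call(pmin, lapply(med, function(m) D[, m])))
    if (cost < best) best <- cost
  }
  best
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

# Spherical Gaussian blobs with given centers (rows) and common sd.
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[g, ], "+")
  }))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Karhunen-Loeve data: mu + sum_k xi_k phi_k on a day grid, with phi_k
# orthonormalized under the given quadrature weights by Gram-Schmidt.
make_kl_data <- function(n, lambdas, p = 182, seed = 1,
                         quadrature = "trapezoid") {
  set.seed(seed)
  grid <- seq_len(p) - 1
  w <- engtraj::quadrature_weights(grid, quadrature)
  raw <- cbind(
    sin(2 * pi * grid / p),
    cos(2 * pi * grid / p),
    sin(4 * pi * grid / p)
  )[, seq_along(lambdas), drop = FALSE]
  phi <- raw
  for (k in seq_len(ncol(phi))) {
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        phi[, k] <- phi[, k] - sum(w * phi[, k] * phi[, j]) * phi[, j]
      }
    }
    phi[, k] <- phi[, k] / sqrt(sum(w * phi[, k]^2))
  }
  mu <- 1 + grid / p
  xi <- sapply(seq_along(lambdas), function(k) rnorm(n, sd = sqrt(lambdas[k])))
  if (n == 1) xi <- matrix(xi, nrow = 1)
  list(
    curves = sweep(xi %*% t(phi), 2, mu, "+"),
    mean = mu, phi = phi, xi = xi, grid = grid, weights = w
  )
}
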