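# Scalar-loop oracles kept deliberately naive and independent of the
# vectorized implementation paths they check.

oracle_design <- function(pts, centers, sigma2) {
  J <- nrow(pts); K <- nrow(centers)
  out <- matrix(NA_real_, J, K)
  for (j in seq_len(J)) for (k in seq_len(K)) {
    d2 <- sum((pts[j, ] - centers[k, ])^2)
    out[j, k] <- exp(-d2 / (2 * sigma2))
  }
  out
}

# per-pair Gaussian density evaluation of the mixture responsibilities
oracle_resp <- function(X, Y, beta, weights = NULL) {
  N <- nrow(X); J <- nrow(Y); p <- ncol(X)
  R <- matrix(NA_real_, N, J)
  for (i in seq_len(N)) {
    dens <- numeric(J)
    for (j in seq_len(J)) {
      wj <- if (is.null(weights)) NULL else weights[[j]]
      w <- if (is.null(wj)) 1 else wj[i]
      dens[j] <- (beta / (2 * pi))^(p / 2) *
        exp(-beta / 2 * w * sum((X[i, ] - Y[j, ])^2))
    }
    R[i, ] <- dens / sum(dens)
  }
  R
}

oracle_loglik <- function(X, Y, beta) {
  N <- nrow(X); J <- nrow(Y); p <- ncol(X)
  ll <- 0
  for (i in seq_len(N)) {
    dens <- numeric(J)
    for (j in seq_len(J))
      dens[j] <- (beta / (2 * pi))^(p / 2) *
        exp(-beta / 2 * sum((X[i, ] - Y[j, ])^2))
    ll <- ll + log(mean(dens))
  }
  ll
}

# sort-based Gini numerator: sum_jk |f_j - f_k| = 2 * sum_i (2i - N - 1) f_(i)
oracle_impi <- function(f, dialect) {
  N <- length(f)
  fs <- sort(f)
  num <- 2 * sum((2 * seq_len(N) - N - 1) * fs)
  denom <- if (dialect == "printed") 2 * N^2 * mean(f) else 2 * N * (N - 1) * mean(f)
  num / denom
}

# small random fitted-ish model for property tests
random_model <- function(seed, N = 12L, p = 3L, grid = c(3L, 3L),
                         basis = c(2L, 2L)) {
  set.seed(seed)
  X <- matrix(rnorm(N * p), N, p)
  g <- make_grid(grid)
  b <- make_basis(g, basis)
  m <- gtm_init(X, g, b)
  m$W <- matrix(rnorm(nrow(m$W) * p, sd = 0.5), nrow(m$W), p)
  m$Y <- m$Phi %*% m$W
  m$beta <- exp(runif(1, -1, 2))
  list(model = m, X = X)
}

five_cluster_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_clusters(seed = 1)
      fit <- gtm_fit(sim$data)
      cache <<- list(sim = sim, fit = fit,
                     coords = project(fit, sim$data))
    }
    cache
  }
})

local_file <- function(name) tempfile(fileext = paste0("-", name))

# central finite differences on the manifold map, independent of the
# analytic kernel derivative
fd_magnification <- function(model, pts, eps = 1e-5) {
  vapply(seq_len(nrow(pts)), function(j) {
    r <- pts[j, ]
    Jac <- sapply(1:2, function(a) {
      e <- c(0, 0); e[a] <- eps
      (v2pigtm:::eval_manifold(model, matrix(r + e, 1)) -
         v2pigtm:::eval_manifold(model, matrix(r - e, 1))) / (2 * eps)
    })
    sqrt(max(det(crossprod(Jac)), 0))
  }, numeric(1))
}

# W fitted to an affine target in the wide-kernel (near-linear) regime;
# sigma2 = 1e3 keeps the design numerically full rank while the residual
# curvature stays below half a percent
near_affine_model <- function(targets_fn, grid_shape = c(5, 5)) {
  g <- make_grid(grid_shape)
  b <- make_basis(g, c(2, 2), sigma2 = 1e3)
  set.seed(1)
  X <- matrix(rnorm(2 * prod(grid_shape)), ncol = 2)
  m <- gtm_init(X, g, b)
  m$W <- qr.solve(m$Phi, targets_fn(g$points))
  m$Y <- m$Phi %*% m$W
  m
}
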