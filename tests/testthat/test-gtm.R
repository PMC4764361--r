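test_that("initialization reproduces planar data and is deterministic", {
  set.seed(3)
  A <- matrix(rnorm(8), 2, 4)
  lat <- matrix(rnorm(100), 50, 2)
  X <- lat %*% A  # exactly 2-D data in 4-D space
  g <- make_grid(c(4, 4)); b <- make_basis(g, c(2, 2))
  m <- gtm_init(X, g, b)
  # the initial manifold lies in the data plane
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr))
  basis4 <- sv$v[, 1:2]
  Yc <- sweep(m$Y, 2, ctr)
  off_plane <- Yc - Yc %*% basis4 %*% t(basis4)
  expect_lt(max(abs(off_plane)), 1e-8)
  expect_true(is.finite(m$beta) && m$beta > 0)
  m2 <- gtm_init(X, g, b)
  expect_identical(m$W, m2$W)
  expect_error(gtm_init(matrix(1, 10, 3), g, b), "variance")
})

test_that("responsibilities normalize, handle degeneracy, and match the oracle", {
  rm <- random_model(11, N = 3L, p = 2L, grid = c(2L, 2L))
  R <- e_step(rm$model, rm$X)
  expect_equal(rowSums(R), rep(1, 3), tolerance = 1e-10)
  expect_equal(R, oracle_resp(rm$X, rm$model$Y, rm$model$beta),
               tolerance = 1e-12)

  # J = 1: all responsibility on the single point
  g1 <- make_grid(c(1, 1)); b1 <- make_basis(g1, c(1, 1), sigma2 = 1)
  m1 <- gtm_init(rm$X, g1, b1)
  expect_equal(unname(e_step(m1, rm$X)), matrix(1, 3, 1))

  # equidistant observation from two manifold points splits evenly
  m2 <- rm$model
  m2$grid$points <- rbind(c(-1, 0), c(1, 0))
  m2$Y <- rbind(c(-1, 0), c(1, 0))
  expect_equal(unname(e_step(m2, matrix(c(0, 5), 1))[1, ]), c(0.5, 0.5))

  # extreme beta must not overflow
  m3 <- rm$model; m3$beta <- 1e8
  R3 <- e_step(m3, rm$X)
  expect_equal(rowSums(R3), rep(1, 3), tolerance = 1e-10)
  expect_true(all(is.finite(R3)))
})

test_that("the M-step solves the weighted normal equations", {
  rm <- random_model(5)
  X <- rm$X; m <- rm$model
  R <- e_step(m, X)
  m2 <- m_step(m, X, R)
  # beta^{-1} equals the responsibility-weighted mean squared residual / p
  D <- as.matrix(dist(rbind(X, m2$Y)))^2
  D <- D[seq_len(nrow(X)), nrow(X) + seq_len(nrow(m2$Y))]
  expect_equal(1 / m2$beta, sum(R * D) / (nrow(X) * ncol(X)),
               tolerance = 1e-12)
  # tiny ridge is a continuous perturbation on well-conditioned systems
  m_a <- m_step(m, X, R, gtm_control(ridge = 0))
  m_b <- m_step(m, X, R, gtm_control(ridge = 1e-12))
  expect_lt(max(abs(m_a$W - m_b$W)), 1e-6)

  # J = 1 with all responsibility on one point collapses to the data mean
  g1 <- make_grid(c(1, 1)); b1 <- make_basis(g1, c(1, 1), sigma2 = 1)
  m1 <- gtm_init(X, g1, b1)
  m1 <- m_step(m1, X, matrix(1, nrow(X), 1), gtm_control(ridge = 0))
  expect_equal(unname(m1$Y[1, ]), unname(colMeans(X)), tolerance = 1e-12)
})

test_that("log-likelihood matches closed forms and the scalar oracle", {
  # single component at the observation, p = 1 ... emulate with p = 2 and
  # beta = 2*pi: density (beta/2pi)^{p/2} exp(0) = 1, log = 0
  g1 <- make_grid(c(1, 1)); b1 <- make_basis(g1, c(1, 1), sigma2 = 1)
  X <- matrix(c(0.3, -0.2), 1)
  m <- gtm_init(rbind(X, X + 1e-9), g1, b1)
  m$W <- matrix(0, nrow(m$W), 2); m$W[1, ] <- X / m$Phi[1, 1]
  m$Y <- m$Phi %*% m$W
  m$beta <- 2 * pi
  expect_equal(log_likelihood(m, X), 0, tolerance = 1e-12)

  rm <- random_model(17, N = 3L, p = 2L, grid = c(2L, 2L))
  expect_equal(log_likelihood(rm$model, rm$X),
               oracle_loglik(rm$X, rm$model$Y, rm$model$beta),
               tolerance = 1e-12)

  # duplicating every lattice point leaves the equal-weight mixture
  # unchanged: the component sum and the 1/J weight both double
  m2 <- rm$model
  m2$Y <- rbind(m2$Y, m2$Y)
  m2$grid$points <- rbind(m2$grid$points, m2$grid$points)
  expect_equal(log_likelihood(m2, rm$X), log_likelihood(rm$model, rm$X),
               tolerance = 1e-12)
})

test_that("EM is monotone, deterministic, and converges on easy data", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(60), 20, 3) + rep(c(0, 4), each = 10)
    f <- gtm_fit(X, grid_shape = c(4, 4), basis_shape = c(2, 2),
                 control = gtm_control(max_iter = 40))
    expect_true(all(diff(f$trace) >= -1e-8 * pmax(abs(f$trace[-length(f$trace)]), 1)))
  }
  X <- matrix(rnorm(60), 20, 3)
  f1 <- gtm_fit(X, grid_shape = c(3, 3), basis_shape = c(2, 2))
  f2 <- gtm_fit(X, grid_shape = c(3, 3), basis_shape = c(2, 2))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$W, f2$W)
})

test_that("posterior summaries and their invariants", {
  rm <- random_model(23, N = 6L)
  m <- rm$model
  # indicator row lands on the lattice point under both summaries
  R <- matrix(0, 1, nrow(m$grid$points)); R[1, 4] <- 1
  expect_equal(unname(project(m, rm$X[1, , drop = FALSE], "mean", resp = R)[1, ]),
               unname(m$grid$points[4, ]))
  expect_equal(unname(project(m, rm$X[1, , drop = FALSE], "mode", resp = R)[1, ]),
               unname(m$grid$points[4, ]))
  # uniform responsibilities on a symmetric lattice give the origin
  Ru <- matrix(1 / 9, 1, 9)
  expect_equal(unname(project(m, rm$X[1, , drop = FALSE], resp = Ru)[1, ]),
               c(0, 0), tolerance = 1e-12)
  # mean projections stay inside the lattice bounding box
  coords <- project(m, rm$X)
  expect_true(all(coords >= -1 - 1e-12 & coords <= 1 + 1e-12))
  # 1-D style arithmetic: responsibilities (0.25, 0.75) on (-1, 1)
  m2 <- m; m2$grid$points <- rbind(c(-1, 0), c(1, 0))
  expect_equal(unname(project(m2, rm$X[1, , drop = FALSE],
                              resp = matrix(c(0.25, 0.75), 1))[1, ]),
               c(0.5, 0), tolerance = 1e-12)
  # mode ties resolve to the lowest lattice index
  Rt <- matrix(c(0.5, 0.5, 0, 0, 0, 0, 0, 0, 0), 1)
  expect_equal(unname(project(m, rm$X[1, , drop = FALSE], "mode", resp = Rt)[1, ]),
               unname(m$grid$points[1, ]))
})

test_that("the fit is equivariant to rigid rotations of the data", {
  set.seed(9)
  X <- matrix(rnorm(90), 30, 3)
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g <- make_grid(c(3, 3)); b <- make_basis(g, c(2, 2))
  m <- gtm_init(X, g, b)
  mr <- m
  mr$W <- m$W %*% Q
  mr$Y <- mr$Phi %*% mr$W
  expect_equal(e_step(m, X), e_step(mr, X %*% Q), tolerance = 1e-12)
  expect_equal(log_likelihood(m, X), log_likelihood(mr, X %*% Q),
               tolerance = 1e-10)
})
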