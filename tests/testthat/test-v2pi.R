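test_that("add_anchor expands the model and pins the moved observation", {
  fc <- five_cluster_fit()
  fit <- fc$fit; X <- fc$sim$data
  J0 <- nrow(fit$grid$points); K0 <- nrow(fit$basis$centers)
  m <- add_anchor(fit, X, 17, c(0.3, -0.4))
  expect_equal(nrow(m$grid$points), J0 + 1L)
  expect_equal(nrow(m$basis$centers), K0 + 1L)
  expect_equal(nrow(m$W), nrow(fit$W) + 1L)
  # zero loading row leaves the manifold intact at the old lattice points
  expect_equal(m$Y[seq_len(J0), ], fit$Y, tolerance = 1e-12)
  # pinned projection is exact, also after further E-steps
  expect_equal(unname(project(m, X)[17, ]), c(0.3, -0.4))
  R <- scaled_e_step(m, X)
  expect_equal(unname(R[17, ]), c(rep(0, J0), 1))
  expect_error(add_anchor(fit, X, 9999, c(0, 0)), "range")
  expect_warning(add_anchor(fit, X, 1, c(5, 5)), "extent")
  # anchoring on an existing lattice point keeps the model valid
  m2 <- add_anchor(fit, X, 3, fit$grid$points[1, ])
  expect_equal(unname(rowSums(scaled_e_step(m2, X))), rep(1, nrow(X)),
               tolerance = 1e-10)
})

test_that("bandwidth_from_neighbors is the m-th neighbour distance", {
  X <- cbind(c(0, 1, 2, 3, 4), 0)  # distances from x1: 1, 2, 3, 4
  expect_equal(bandwidth_from_neighbors(X, 1, 3), 3)
  expect_equal(bandwidth_from_neighbors(X, 1, 1), 1)
  expect_error(bandwidth_from_neighbors(X, 1, 5), "\\[1, N-1\\]")
  # ties: the smaller distance fills the rank
  Xt <- cbind(c(0, 1, 1, 2), 0)
  expect_equal(bandwidth_from_neighbors(Xt, 1, 2), 1)
})

test_that("scaling families follow their closed forms", {
  X <- cbind(c(0, 10, 20, 40), 0)
  sw <- scaling_weights(X, 1, "delta3", h = 20)
  expect_equal(sw$values, c(0, 0.125, 1, 8))
  expect_equal(scaling_weights(X, 1, "delta", h = 20)$values, c(0, 0.5, 1, 2))
  expect_equal(scaling_weights(X, 1, "delta2", h = 20)$values, c(0, 0.25, 1, 4))
  # Delta = 1 maps to 1 under every power family; exp families at 0 give 0
  for (fam in c("delta", "delta2", "delta3"))
    expect_equal(scaling_weights(X, 1, fam, h = 20)$values[3], 1)
  expect_equal(scaling_weights(X, 1, "exp_inv", h = 20)$values[1], 0)
  expect_equal(scaling_weights(X, 1, "exp_inv2", h = 20)$values[1], 0)
  expect_equal(scaling_weights(X, 1, "exp_inv", h = 20)$values[3], exp(-1))
  expect_equal(scaling_weights(X, 1, "none")$values, rep(1, 4))
  expect_error(scaling_weights(X, 1, "delta", h = -1), "positive")
  expect_error(scaling_weights(X, 1, "delta"), "exactly one")
})

test_that("scaled E-step matches the modified-density oracle and reduces to e_step", {
  rm <- random_model(42, N = 4L, p = 3L)
  X <- rm$X
  m <- add_anchor(rm$model, X, 2, c(0.2, 0.2))
  m$beta <- 1.3
  sw <- scaling_weights(X, 2, "delta2", h = 1.5)
  m$anchors[[1]]$weights <- sw$values
  R <- scaled_e_step(m, X)
  J <- nrow(m$Y)
  wl <- c(rep(list(NULL), J - 1L), list(sw$values))
  ref <- oracle_resp(X, m$Y, m$beta, weights = wl)
  ref[2, ] <- c(rep(0, J - 1L), 1)  # pinned row
  expect_equal(R, ref, tolerance = 1e-12)
  # weights identically one reduce to the plain E-step
  m$anchors[[1]]$weights <- rep(1, 4)
  expect_identical(scaled_e_step(m, X), e_step(m, X))
  # zero weight gives that observation the maximal unnormalized kernel at
  # the anchor column: exponent 0 is the row maximum
  m$anchors[[1]]$weights <- c(0, 0, 1, 1)
  E <- -m$beta / 2 * v2pigtm:::sq_dist(X, m$Y)
  E[, J] <- E[, J] * m$anchors[[1]]$weights
  expect_equal(max(E[1, ]), E[1, J])
})

test_that("conditional refit ascends its objective and respects the pin", {
  fc <- five_cluster_fit()
  fit <- fc$fit; X <- fc$sim$data
  m <- add_anchor(fit, X, 5, c(0.8, 0.8))
  sw <- scaling_weights(X, 5, "delta3", neighbors = 20)
  m$anchors[[1]]$weights <- sw$values
  m <- conditional_refit(m, X)
  tr <- m$refit_trace
  expect_true(all(diff(tr) >= -1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  expect_equal(unname(project(m, X)[5, ]), c(0.8, 0.8))
})

test_that("anchoring at the current projection perturbs far less than a cross-view move", {
  fc <- five_cluster_fit()
  fit <- fc$fit; X <- fc$sim$data
  i <- 40
  at_self <- move_point(fit, X, i, fc$coords[i, ], stage = 1)
  across <- move_point(fit, X, i, c(0.95, 0.95), stage = 1)
  Y_pre <- function(target) rbind(fit$Y, v2pigtm:::eval_manifold(fit, matrix(target, 1)))
  rms_self <- sqrt(mean((at_self$model$Y - Y_pre(fc$coords[i, ]))^2))
  rms_across <- sqrt(mean((across$model$Y - Y_pre(c(0.95, 0.95)))^2))
  expect_lt(rms_self, rms_across)
})

test_that("blending weights and the manifold mixture behave as a convex blend", {
  g <- make_grid(c(20, 20))
  r_star <- c(0.31, -0.12)
  bw <- blend_weights(g$points, r_star)
  expect_true(all(bw$delta >= 0 & bw$delta <= 1))
  expect_identical(max(bw$delta), 1)  # attained exactly
  set.seed(6)
  cur <- matrix(rnorm(400 * 3), 400, 3)
  usr <- matrix(rnorm(400 * 3), 400, 3)
  out <- blend_manifolds(cur, usr, g$points, r_star)
  far <- which.max(bw$delta)
  expect_identical(out[far, ], cur[far, ])  # bit-identical at delta = 1
  # identity when the two manifolds agree
  expect_equal(blend_manifolds(cur, cur, g$points, r_star), cur)
  # every output row lies on the segment between the input rows
  lo <- pmin(cur, usr); hi <- pmax(cur, usr)
  expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
  # a point coinciding with r_star takes the user-adjusted row
  g2 <- g; pts <- rbind(g$points, r_star)
  cur2 <- rbind(cur, c(1, 2, 3)); usr2 <- rbind(usr, c(4, 5, 6))
  out2 <- blend_manifolds(cur2, usr2, pts, r_star)
  expect_identical(out2[401, ], usr2[401, ])
  # delta = 0.5 averages
  pts3 <- rbind(c(0, 0), c(1, 0), c(2, 0))
  out3 <- blend_manifolds(matrix(0, 3, 1), matrix(2, 3, 1), pts3, c(0, 0))
  expect_equal(out3[2, 1], 1)
  expect_warning(blend_manifolds(cur[1, , drop = FALSE], usr[1, , drop = FALSE],
                                 matrix(r_star, 1), r_star), "coincide")
})

test_that("stage-1 moves pull the nearest high-dimensional neighbour along", {
  fc <- five_cluster_fit()
  fit <- fc$fit; X <- fc$sim$data
  i <- which(fc$sim$labels == 1)[1]
  target <- c(-0.9, -0.9)
  dh <- sqrt(colSums((t(X) - X[i, ])^2)); dh[i] <- Inf
  nn <- which.min(dh)
  res <- move_point(fit, X, i, target, stage = 1)
  d_before <- sqrt(sum((fc$coords[nn, ] - target)^2))
  d_after <- sqrt(sum((res$coordinates[nn, ] - target)^2))
  expect_lt(d_after, d_before)
  expect_equal(unname(res$coordinates[i, ]), target)
})

test_that("stage-3 moves attract the cluster and stay local far away", {
  fc <- five_cluster_fit()
  fit <- fc$fit; X <- fc$sim$data
  i <- which(fc$sim$labels == 1)[1]
  target <- c(-0.9, -0.9)
  res <- move_point(fit, X, i, target, stage = 3, family = "delta3",
                    neighbors = 20)
  mates <- setdiff(which(fc$sim$labels == 1), i)
  d0 <- mean(sqrt(colSums((t(fc$coords[mates, ]) - target)^2)))
  d1 <- mean(sqrt(colSums((t(res$coordinates[mates, ]) - target)^2)))
  expect_lt(d1, d0)
  # columns at delta = 1 are bit-unchanged (locality of the blend)
  bw <- blend_weights(res$model$grid$points, target)
  far <- which(bw$delta == 1)
  expect_identical(res$model$Y[far, ], fit$Y[far, ])
})

test_that("sequential moves compose and replay bit-exactly", {
  fc <- five_cluster_fit()
  fit <- fc$fit; X <- fc$sim$data
  r1 <- move_point(fit, X, 10, c(-0.8, 0.6), stage = 3, neighbors = 20)
  r2 <- move_point(r1$model, X, 95, c(0.7, -0.7), stage = 3, neighbors = 20)
  expect_equal(nrow(r2$model$grid$points), nrow(fit$grid$points) + 2L)
  expect_equal(nrow(r2$model$basis$centers), nrow(fit$basis$centers) + 2L)
  expect_length(r2$model$log, 2L)
  replayed <- replay_moves(fit, X, r2$model$log)
  expect_identical(replayed$W, r2$model$W)
  expect_identical(replayed$Y, r2$model$Y)
  expect_identical(replayed$beta, r2$model$beta)
})
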