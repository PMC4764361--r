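#' Anchor an observation at user-chosen latent coordinates
#'
#' Implements the basic interaction step: the lattice gains a point `r_star`
#' (J grows by one), the basis gains an attractor kernel centered there with
#' the model's width (K grows by one), the loading matrix gains a zero
#' column for the new kernel so the manifold is initially unchanged, and the
#' moved observation's responsibility row is pinned to the indicator of the
#' new lattice point in every subsequent E-step, so its posterior-mean
#' projection equals `r_star` exactly.
#'
#' @param model a fitted `gtm`.
#' @param data numeric matrix N x p the model was fitted to.
#' @param obs_index index (1-based) of the moved observation.
#' @param latent_target length-2 latent coordinates `r_star`.
#' @return The expanded `gtm` model.
#' @export
add_anchor <- function(model, data, obs_index, latent_target) {
  X <- as_data_matrix(data)
  obs_index <- as.integer(obs_index)
  if (length(obs_index) != 1L || is.na(obs_index) ||
      obs_index < 1L || obs_index > nrow(X))
    stop("'obs_index' out of range")
  r_star <- as.numeric(latent_target)
  if (length(r_star) != 2L || any(!is.finite(r_star)))
    stop("'latent_target' must be 2 finite coordinates")
  ext <- model$grid$extent
  if (r_star[1L] < ext[1L, 1L] || r_star[1L] > ext[1L, 2L] ||
      r_star[2L] < ext[2L, 1L] || r_star[2L] > ext[2L, 2L])
    warning("anchor target lies outside the lattice extent")

  K <- nrow(model$basis$centers)
  model$grid$points <- rbind(model$grid$points, r_star)
  rownames(model$grid$points) <- NULL
  model$basis$centers <- rbind(model$basis$centers, r_star)
  rownames(model$basis$centers) <- NULL
  # zero loading row for the new kernel; bias row (if any) stays last
  Wk <- model$W[seq_len(K), , drop = FALSE]
  Wrest <- if (nrow(model$W) > K) model$W[-seq_len(K), , drop = FALSE] else NULL
  model$W <- rbind(Wk, 0, Wrest)
  model$Phi <- design_matrix(model$basis, model$grid$points)
  model$Y <- model$Phi %*% model$W
  model$blended <- FALSE

  j_new <- nrow(model$grid$points)
  model$anchors <- c(model$anchors, list(list(
    obs = obs_index, r_star = r_star, grid_index = j_new,
    basis_index = K + 1L, weights = NULL, family = "none", h = NA_real_)))
  prev <- match(obs_index, model$pin_obs)
  if (!is.na(prev)) {
    model$pin_col[prev] <- j_new
  } else {
    model$pin_obs <- c(model$pin_obs, obs_index)
    model$pin_col <- c(model$pin_col, j_new)
  }
  model
}

#' Bandwidth from a nearest-neighbour count
#'
#' Resolves the scaling bandwidth `h` as the Euclidean distance from the
#' moved observation to its m-th nearest other observation, so that at
#' least m points fall within one bandwidth of it.
#'
#' @param data numeric matrix N x p.
#' @param obs_index index of the moved observation.
#' @param m neighbour count, `1 <= m <= N - 1`.
#' @return Positive scalar bandwidth.
#' @export
bandwidth_from_neighbors <- function(data, obs_index, m) {
  X <- as_data_matrix(data)
  N <- nrow(X)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > N - 1L)
    stop("'m' must lie in [1, N-1]")
  d <- sqrt(rowSums(sweep(X, 2L, X[obs_index, ], "-")^2))[-obs_index]
  sort(d, method = "radix")[m]
}

v_families <- c("delta", "delta2", "delta3", "exp_inv", "exp_inv2", "none")

#' Local scaling weights V(Delta)
#'
#' Evaluates the scaling function on standardized data-space distances to
#' the moved observation, `Delta_i = ||x_star - x_i|| / h`. Small weights
#' near the moved point flatten the residual penalty of the anchor
#' component there, raising its responsibility, so similar observations are
#' pulled toward the anchor; large weights push dissimilar observations
#' away. Exponential families are defined as 0 at `Delta = 0` by continuity.
#'
#' @param data numeric matrix N x p.
#' @param obs_index index of the moved observation `x_star`.
#' @param family one of `"delta"`, `"delta2"`, `"delta3"`, `"exp_inv"`,
#'   `"exp_inv2"`, `"none"` (all ones).
#' @param h positive bandwidth; give either `h` or `neighbors`.
#' @param neighbors neighbour count from which `h` is derived via
#'   [bandwidth_from_neighbors()].
#' @return List with `values` (N-vector of nonnegative weights), `family`,
#'   `h`.
#' @export
scaling_weights <- function(data, obs_index, family = "delta3", h = NULL,
                            neighbors = NULL) {
  family <- match.arg(family, v_families)
  X <- as_data_matrix(data)
  if (family == "none")
    return(list(values = rep(1, nrow(X)), family = family, h = NA_real_))
  if (is.null(h) == is.null(neighbors))
    stop("give exactly one of 'h' or 'neighbors'")
  if (is.null(h)) h <- bandwidth_from_neighbors(X, obs_index, neighbors)
  if (!is.finite(h) || h <= 0) stop("'h' must be positive")
  delta <- unname(sqrt(rowSums(sweep(X, 2L, X[obs_index, ], "-")^2))) / h
  v <- switch(family,
    delta = delta,
    delta2 = delta^2,
    delta3 = delta^3,
    exp_inv = ifelse(delta == 0, 0, exp(-1 / delta)),
    exp_inv2 = ifelse(delta == 0, 0, exp(-1 / delta^2)))
  list(values = v, family = family, h = h)
}

#' E-step with locally scaled anchor components
#'
#' Identical to [e_step()] except that each anchor component's squared
#' residual is multiplied by that anchor's scaling weights,
#' `exp(-beta/2 V(Delta_i) ||x_i - y_star||^2)`; all other components use
#' the unscaled Gaussian density. With weights identically 1 (or no
#' anchors) this reduces exactly to [e_step()].
#'
#' @inheritParams e_step
#' @return N x J responsibility matrix; rows sum to 1; pinned rows are
#'   indicators.
#' @export
scaled_e_step <- function(model, data) {
  X <- as_data_matrix(data)
  R <- row_softmax(exponent_matrix(model, X, scaled = TRUE))
  apply_pins(model, R)
}

# effective responsibilities for the M-step under scaling: anchor columns
# multiplied by their weights (the expected complete-data objective weights
# each residual by R_ij * V_ij)
effective_resp <- function(model, R) {
  for (a in model$anchors)
    if (!is.null(a$weights)) R[, a$grid_index] <- R[, a$grid_index] * a$weights
  R
}

#' Conditionally refit an anchored model
#'
#' Runs EM holding the anchor's latent point and attractor center fixed:
#' alternates [scaled_e_step()] with the weighted M-step until the relative
#' change in the constrained objective falls below `control$rel_tol`. The
#' objective (scaled pseudo log-likelihood with pinned rows) is
#' non-decreasing across iterations.
#'
#' @param model an anchored `gtm` (see [add_anchor()]).
#' @param data numeric matrix N x p.
#' @param control a `gtm_control`; defaults to the model's.
#' @return The refit model, with the objective trace in `refit_trace`.
#' @export
conditional_refit <- function(model, data, control = model$control) {
  X <- as_data_matrix(data)
  trace <- numeric(control$max_iter)
  obj_old <- -Inf
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    R <- scaled_e_step(model, X)
    model <- m_step(model, X, effective_resp(model, R), control)
    obj <- v2pi_objective(model, X)
    trace[iter] <- obj
    if (is.finite(obj_old) &&
        abs(obj - obj_old) < control$rel_tol * (abs(obj_old) + 1e-10))
      break
    obj_old <- obj
  }
  model$refit_trace <- trace[seq_len(iter)]
  model$refit_iterations <- iter
  model
}

#' Latent blending weights
#'
#' Computes `delta_j = ||r_j - r_star|| / b` with
#' `b = max_j ||r_j - r_star||`, so that `delta` lies in [0, 1] and attains
#' 1 at the lattice point farthest from the anchor.
#'
#' @param points J x 2 matrix of lattice points.
#' @param r_star length-2 anchor coordinates.
#' @return List with `delta` (J-vector) and `b` (the normalizer).
#' @export
blend_weights <- function(points, r_star) {
  d <- sqrt(rowSums(sweep(as.matrix(points), 2L, as.numeric(r_star), "-")^2))
  b <- max(d)
  list(delta = if (b > 0) d / b else d * 0, b = b)
}

#' Blend current and user-adjusted manifolds
#'
#' Forms the mixture-of-manifolds estimate
#' `y_j(new) = delta_j y_j(current) + (1 - delta_j) y_j(user)` per lattice
#' point, with [blend_weights()] taken over the expanded lattice. Columns at
#' maximal latent distance from the anchor (`delta = 1`) are returned
#' bit-identical to the current manifold, so the visual change stays local
#' to the anchor.
#'
#' @param current J x p manifold before the interaction (rows = lattice
#'   points).
#' @param user_adjusted J x p manifold after the conditional refit.
#' @param points J x 2 lattice points (expanded, including the anchor).
#' @param r_star length-2 anchor coordinates.
#' @return J x p blended manifold.
#' @export
blend_manifolds <- function(current, user_adjusted, points, r_star) {
  current <- as.matrix(current); user_adjusted <- as.matrix(user_adjusted)
  if (!all(dim(current) == dim(user_adjusted)))
    stop("manifold dimensions must match")
  bw <- blend_weights(points, r_star)
  if (bw$b == 0) {
    warning("all lattice points coincide with the anchor; returning the user-adjusted manifold")
    return(user_adjusted)
  }
  current * bw$delta + user_adjusted * (1 - bw$delta)
}

# manifold evaluated at arbitrary latent points with the model's loadings
eval_manifold <- function(model, points) {
  design_matrix(model$basis, as.matrix(points)) %*% model$W
}

#' Move one plotted observation and update the model
#'
#' The complete interaction: [add_anchor()] at the user-chosen latent
#' target, local scaling weights per `family`/bandwidth, a conditional
#' refit, and (stage 3) blending of the pre-move and refit manifolds with
#' projections recomputed from the blend. Stage 1 skips scaling (V = 1);
#' stage 2 skips blending. Repeated calls compose: the lattice and basis
#' each grow by one per move and the interaction log accumulates on the
#' model, so a log can be replayed deterministically.
#'
#' @param model a fitted `gtm`.
#' @param data numeric matrix N x p.
#' @param obs_index index of the observation to move.
#' @param latent_target length-2 latent destination `r_star`.
#' @param family scaling family, see [scaling_weights()]; ignored at
#'   stage 1.
#' @param h,neighbors bandwidth specification (one of the two); default is
#'   the distance to the 20th nearest neighbour.
#' @param stage 1 (anchor only), 2 (anchor + scaling) or 3 (full, default).
#' @param control a `gtm_control`; defaults to the model's.
#' @return List with `model` (updated `gtm`), `coordinates` (N x 2
#'   posterior-mean projections), `magnification` (per lattice point) and
#'   `record` (the interaction record, also appended to `model$log`).
#' @export
move_point <- function(model, data, obs_index, latent_target,
                       family = "delta3", h = NULL, neighbors = NULL,
                       stage = 3L, control = model$control) {
  stage <- as.integer(stage)
  if (!stage %in% 1:3) stop("'stage' must be 1, 2 or 3")
  X <- as_data_matrix(data)
  pre <- model
  model <- add_anchor(model, X, obs_index, latent_target)
  a <- length(model$anchors)
  if (stage >= 2L) {
    if (is.null(h) && is.null(neighbors)) neighbors <- 20L
    sw <- scaling_weights(X, obs_index, family, h = h, neighbors = neighbors)
    model$anchors[[a]]$weights <- sw$values
    model$anchors[[a]]$family <- sw$family
    model$anchors[[a]]$h <- sw$h
  }
  model <- conditional_refit(model, X, control)
  if (stage == 3L) {
    # pre-move manifold on the expanded lattice: cached (possibly blended)
    # rows for existing points, parametric evaluation at the new anchor
    Y_cur <- rbind(pre$Y, eval_manifold(pre, matrix(latent_target, 1L)))
    model$Y <- blend_manifolds(Y_cur, model$Y, model$grid$points,
                               latent_target)
    model$blended <- TRUE
  }
  record <- list(obs_index = obs_index,
                 obs_id = if (!is.null(model$obs_ids)) model$obs_ids[obs_index] else NULL,
                 target = as.numeric(latent_target), stage = stage,
                 family = model$anchors[[a]]$family,
                 h = model$anchors[[a]]$h,
                 refit_iterations = model$refit_iterations)
  model$log <- c(model$log, list(record))
  list(model = model,
       coordinates = project(model, X),
       magnification = magnification(model),
       record = record)
}

#' Replay an interaction log
#'
#' Applies a sequence of recorded moves to a freshly fitted model. Replaying
#' the log of a session reproduces its final model exactly.
#'
#' @param model a fitted `gtm` without anchors.
#' @param data numeric matrix N x p.
#' @param log list of interaction records as produced by [move_point()]
#'   (fields `obs_index`, `target`, `stage`, `family`, `h`).
#' @return The model after all moves.
#' @export
replay_moves <- function(model, data, log) {
  for (rec in log) {
    model <- move_point(model, data, rec$obs_index, rec$target,
                        family = rec$family,
                        h = if (is.finite(rec$h)) rec$h else NULL,
                        neighbors = if (is.finite(rec$h)) NULL else 20L,
                        stage = rec$stage)$model
  }
  model
}
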