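#' Fitting controls for GTM
#'
#' @param max_iter maximum number of EM iterations.
#' @param rel_tol stop when the relative change in log-likelihood between
#'   iterations falls below this value.
#' @param ridge nonnegative ridge added to the M-step normal equations;
#'   guards against ill-conditioning when the basis is nearly collinear.
#' @param seed integer seed recorded with the model (the fit itself is
#'   deterministic; the seed governs any downstream stochastic steps such as
#'   k-means restarts).
#' @return A list of class `gtm_control`.
#' @export
gtm_control <- function(max_iter = 200L, rel_tol = 1e-5, ridge = 1e-6,
                        seed = 1L) {
  stopifnot(max_iter >= 1L, rel_tol > 0, ridge >= 0)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 ridge = ridge, seed = as.integer(seed)),
            class = "gtm_control")
}

as_data_matrix <- function(data) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("data contains non-finite entries")
  if (ncol(X) < 2L) stop("data must have at least 2 variables (p >= q = 2)")
  X
}

#' Initialize a GTM model from principal components
#'
#' Chooses the loading matrix W so that the initial manifold approximates the
#' plane spanned by the top two principal components of the data: each
#' lattice point `r_j` is mapped to
#' `mean(x) + U L^{1/2} r_j` (U the leading eigenvectors, L the eigenvalues)
#' and W is the least-squares fit of the basis expansion to those targets.
#' The noise precision `beta` is initialized to the inverse of the larger of
#' the third principal eigenvalue and half the mean squared spacing between
#' adjacent manifold points, so the mixture components overlap their
#' neighbours at the start.
#'
#' @param data numeric matrix, observations in rows (N x p, p >= 2).
#' @param lattice a `gtm_grid`.
#' @param basis a `gtm_basis`.
#' @param control a `gtm_control`.
#' @return An unfitted object of class `gtm`.
#' @export
gtm_init <- function(data, lattice, basis, control = gtm_control()) {
  X <- as_data_matrix(data)
  N <- nrow(X); p <- ncol(X)
  if (N < 2L) stop("need at least 2 observations")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (all(abs(Xc) < .Machine$double.eps * 100))
    stop("data has zero variance; cannot initialize")
  sv <- svd(Xc, nu = 0, nv = min(3L, p))
  eig <- sv$d^2 / N                      # principal eigenvalues
  q <- 2L
  U <- sv$v[, seq_len(q), drop = FALSE]
  scl <- sqrt(pmax(eig[seq_len(q)], .Machine$double.eps))
  # PCA-plane targets for each lattice point
  targets <- sweep(lattice$points %*% diag(scl, q) %*% t(U), 2L, ctr, "+")
  Phi <- design_matrix(basis, lattice)
  W <- ridge_solve(crossprod(Phi), crossprod(Phi, targets), control$ridge)
  Y <- Phi %*% W
  lam3 <- if (p > q && length(eig) >= q + 1L) eig[q + 1L] else 0
  grid_sp <- neighbor_spacing(lattice, Y)
  beta_inv <- max(lam3, grid_sp / 2)
  if (beta_inv <= 0) beta_inv <- mean(Xc^2)
  model <- structure(list(
    grid = lattice, basis = basis, Phi = Phi, W = W, Y = Y,
    beta = 1 / beta_inv,
    anchors = list(), pin_obs = integer(0), pin_col = integer(0),
    blended = FALSE,
    var_names = colnames(X), obs_ids = rownames(X),
    trace = numeric(0), converged = NA, iterations = 0L,
    control = control), class = "gtm")
  model
}

# mean squared distance between manifold points adjacent on the grid
neighbor_spacing <- function(lattice, Y) {
  sh <- lattice$shape
  idx <- matrix(seq_len(nrow(Y)), nrow = sh[1L], ncol = sh[2L], byrow = TRUE)
  d2 <- c()
  if (sh[2L] > 1L)
    d2 <- c(d2, rowSums((Y[idx[, -1L], , drop = FALSE] -
                         Y[idx[, -sh[2L]], , drop = FALSE])^2))
  if (sh[1L] > 1L)
    d2 <- c(d2, rowSums((Y[idx[-1L, ], , drop = FALSE] -
                         Y[idx[-sh[1L], ], , drop = FALSE])^2))
  if (length(d2) == 0L) 0 else mean(d2)
}

ridge_solve <- function(A, B, ridge) {
  Ar <- A + diag(ridge, nrow(A))
  out <- tryCatch(solve(Ar, B), error = function(e) e)
  if (inherits(out, "error"))
    stop("singular M-step normal equations; raise 'ridge' in gtm_control()")
  out
}

# log-density exponents E[i, j] = -beta/2 * w_ij * ||x_i - y_j||^2, with
# w_ij = 1 except for anchor columns under scaling
exponent_matrix <- function(model, X, scaled) {
  E <- -model$beta / 2 * sq_dist(X, model$Y)
  if (scaled && length(model$anchors)) {
    for (a in model$anchors) {
      if (!is.null(a$weights)) E[, a$grid_index] <- E[, a$grid_index] * a$weights
    }
  }
  E
}

apply_pins <- function(model, R) {
  if (length(model$pin_obs)) {
    R[model$pin_obs, ] <- 0
    R[cbind(model$pin_obs, model$pin_col)] <- 1
  }
  R
}

row_softmax <- function(E) {
  mx <- apply(E, 1L, max)
  R <- exp(E - mx)
  R / rowSums(R)
}

#' E-step: posterior responsibilities
#'
#' Computes the N x J matrix of posterior probabilities that lattice point j
#' generated observation i, `R_ij` proportional to
#' `exp(-beta/2 ||x_i - y_j||^2)` row-normalized (the shared Gaussian
#' prefactor cancels). Computed with a per-row max shift for overflow safety.
#' Rows of observations pinned by an interaction anchor are set to the
#' indicator of their anchor's lattice point.
#'
#' @param model a `gtm` model.
#' @param data numeric matrix N x p.
#' @return N x J responsibility matrix; rows sum to 1.
#' @export
e_step <- function(model, data) {
  X <- as_data_matrix(data)
  R <- row_softmax(exponent_matrix(model, X, scaled = FALSE))
  apply_pins(model, R)
}

#' M-step: update loadings and noise precision
#'
#' Solves the responsibility-weighted least-squares problem
#' `(Phi' G Phi + ridge I) W = Phi' R' X` with `G = diag(colSums(R))`, then
#' updates `beta^{-1}` to the responsibility-weighted mean squared residual
#' per data dimension. Accepts an effective responsibility matrix whose rows
#' need not sum to one (locally scaled interactions multiply rows by the
#' scaling weights).
#'
#' @param model a `gtm` model.
#' @param data numeric matrix N x p.
#' @param resp N x J (effective) responsibility matrix.
#' @param control a `gtm_control`; defaults to the model's own.
#' @return The model with updated `W`, `Y` and `beta`.
#' @export
m_step <- function(model, data, resp, control = model$control) {
  X <- as_data_matrix(data)
  g <- colSums(resp)
  Phi <- model$Phi
  A <- crossprod(Phi, Phi * g)
  B <- crossprod(Phi, crossprod(resp, X))
  W <- ridge_solve(A, B, control$ridge)
  Y <- Phi %*% W
  wsq <- sum(resp * sq_dist(X, Y))
  model$W <- W
  model$Y <- Y
  model$beta <- nrow(X) * ncol(X) / wsq
  model$blended <- FALSE
  model
}

#' Mixture log-likelihood of a GTM model
#'
#' Evaluates `sum_i log( (1/J) sum_j p(x_i | y_j, beta) )` with the Gaussian
#' component density of the model, in log space.
#'
#' @param model a `gtm` model.
#' @param data numeric matrix N x p.
#' @return A scalar log-likelihood.
#' @export
log_likelihood <- function(model, data) {
  X <- as_data_matrix(data)
  p <- ncol(X)
  E <- -model$beta / 2 * sq_dist(X, model$Y)
  mx <- apply(E, 1L, max)
  lse <- mx + log(rowSums(exp(E - mx)))
  sum(lse) + nrow(X) * (p / 2 * log(model$beta / (2 * pi)) - log(ncol(E)))
}

# objective maximized by the conditional (anchored, scaled) EM: pinned rows
# contribute only their anchor component's (scaled) density
v2pi_objective <- function(model, X) {
  p <- ncol(X)
  E <- exponent_matrix(model, X, scaled = TRUE)
  J <- ncol(E)
  free <- setdiff(seq_len(nrow(X)), model$pin_obs)
  val <- 0
  if (length(free)) {
    Ef <- E[free, , drop = FALSE]
    mx <- apply(Ef, 1L, max)
    val <- val + sum(mx + log(rowSums(exp(Ef - mx))))
  }
  if (length(model$pin_obs))
    val <- val + sum(E[cbind(model$pin_obs, model$pin_col)])
  val + nrow(X) * (p / 2 * log(model$beta / (2 * pi)) - log(J))
}

#' Fit a GTM model by EM
#'
#' Alternates the E- and M-steps from a principal-component initialization
#' until the relative change in log-likelihood drops below
#' `control$rel_tol` or `control$max_iter` is reached. The fit is
#' deterministic: identical data and controls give identical models.
#'
#' @param data numeric matrix or data frame, observations in rows.
#' @param lattice a `gtm_grid`; built from `grid_shape` when `NULL`.
#' @param basis a `gtm_basis`; built from `basis_shape` when `NULL`.
#' @param grid_shape,basis_shape,width_factor,extent convenience arguments
#'   used when `lattice`/`basis` are not supplied; defaults give the usual
#'   J = 400 lattice with K = 16 attractors.
#' @param control a `gtm_control`.
#' @return A fitted `gtm` with elements `trace` (per-iteration
#'   log-likelihood), `converged` and `iterations`.
#' @examples
#' sim <- simulate_clusters()
#' fit <- gtm_fit(sim$data, grid_shape = c(10, 10), basis_shape = c(4, 4))
#' head(project(fit, sim$data))
#' @export
gtm_fit <- function(data, lattice = NULL, basis = NULL,
                    grid_shape = c(20L, 20L), basis_shape = c(4L, 4L),
                    width_factor = 1, extent = c(-1, 1),
                    control = gtm_control()) {
  if (is.null(lattice)) lattice <- make_grid(grid_shape, extent)
  if (is.null(basis)) basis <- make_basis(lattice, basis_shape, width_factor)
  X <- as_data_matrix(data)
  model <- gtm_init(X, lattice, basis, control)
  trace <- numeric(control$max_iter)
  converged <- FALSE
  ll_old <- -Inf
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    R <- e_step(model, X)
    model <- m_step(model, X, R, control)
    ll <- log_likelihood(model, X)
    trace[iter] <- ll
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < control$rel_tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  model$trace <- trace[seq_len(iter)]
  model$converged <- converged
  model$iterations <- iter
  model
}

#' @export
print.gtm <- function(x, ...) {
  cat("Generative topographic mapping model\n")
  cat(sprintf("  lattice: %d x %d (J = %d), basis: K = %d, sigma2 = %.4g\n",
              x$grid$shape[1L], x$grid$shape[2L], nrow(x$grid$points),
              nrow(x$basis$centers), x$basis$sigma2))
  cat(sprintf("  data dimension p = %d, beta = %.4g\n", ncol(x$W), x$beta))
  if (length(x$anchors))
    cat(sprintf("  interaction anchors: %d (lattice/basis expanded)\n",
                length(x$anchors)))
  if (x$blended) cat("  manifold: blended (post-interaction mixture)\n")
  if (length(x$trace))
    cat(sprintf("  EM: %d iterations, converged = %s, logLik = %.4f\n",
                x$iterations, x$converged, x$trace[length(x$trace)]))
  invisible(x)
}
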