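#' Project observations into latent space
#'
#' Summarizes each observation's posterior distribution over lattice points
#' as a 2-D display coordinate: the posterior mean `sum_j R_ij r_j`
#' (default, the usual plotted summary) or the posterior mode (the lattice
#' point of maximal responsibility, ties broken by lowest lattice index).
#'
#' @param model a fitted `gtm`.
#' @param data numeric matrix N x p.
#' @param mode `"mean"` or `"mode"`.
#' @param resp optional precomputed responsibility matrix; when omitted the
#'   model's (scaled, pinned) E-step is run.
#' @return N x 2 matrix of latent coordinates, columns `q1`, `q2`.
#' @export
project <- function(model, data, mode = c("mean", "mode"), resp = NULL) {
  mode <- match.arg(mode)
  if (is.null(resp)) resp <- scaled_e_step(model, data)
  pts <- model$grid$points
  coords <- if (mode == "mean") {
    resp %*% pts
  } else {
    pts[apply(resp, 1L, which.max), , drop = FALSE]
  }
  dimnames(coords) <- list(rownames(data), c("q1", "q2"))
  coords
}

#' Manifold magnification factors
#'
#' Computes, at every lattice point, the local areal stretch of the
#' latent-to-data mapping: `sqrt(det(J'J))` where `J = dy/dr` is the p x 2
#' Jacobian of the manifold, using the analytic kernel derivative
#' `dPhi_k/dr = -((r - mu_k)/sigma^2) Phi_k(r)`. Flat regions of the
#' manifold give small constant factors; hills and folds give large ones.
#'
#' @param model a fitted `gtm`.
#' @param points optional matrix of latent points (rows); defaults to the
#'   model's lattice.
#' @return Numeric vector of nonnegative factors, one per point. Factors that
#'   are exactly 0 indicate a rank-deficient Jacobian and carry a
#'   `"degenerate"` attribute marking the affected points.
#' @export
magnification <- function(model, points = NULL) {
  pts <- if (is.null(points)) model$grid$points else as.matrix(points)
  centers <- model$basis$centers
  sigma2 <- model$basis$sigma2
  K <- nrow(centers)
  Phi <- basis_eval(pts, centers, sigma2)
  W <- model$W[seq_len(K), , drop = FALSE]  # bias column has zero derivative
  fac <- vapply(seq_len(nrow(pts)), function(j) {
    diff <- sweep(centers, 2L, pts[j, ], "-")          # mu_k - r
    dPhi <- (diff / sigma2) * Phi[j, ]                 # K x 2, d/dr of kernel
    Jac <- crossprod(W, dPhi)                          # p x 2 via t(W) %*% dPhi
    det_g <- det(crossprod(Jac))
    if (det_g < 0) det_g <- 0
    sqrt(det_g)
  }, numeric(1))
  degen <- fac == 0
  if (any(degen)) attr(fac, "degenerate") <- which(degen)
  fac
}

#' Convenience scatter of a GTM view
#'
#' Plots posterior-mean projections, optionally colored by labels, over the
#' lattice extent.
#'
#' @param x a fitted `gtm`.
#' @param data the data matrix the model was fitted to.
#' @param labels optional factor used to color points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gtm <- function(x, data, labels = NULL, ...) {
  coords <- project(x, data)
  col <- if (is.null(labels)) 1L else as.integer(factor(labels))
  graphics::plot(coords, col = col, pch = 19,
                 xlim = x$grid$extent[1L, ], ylim = x$grid$extent[2L, ],
                 xlab = "q1", ylab = "q2", ...)
  invisible(coords)
}
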