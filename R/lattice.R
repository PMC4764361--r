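#' Build a regular latent lattice
#'
#' Constructs the regular rectangular grid of latent points that indexes the
#' mixture components of a GTM model. Points are returned in row-major order
#' (rows of the grid vary slowest) and span `extent` exactly; a 1x1 grid sits
#' at the midpoint of the extent.
#'
#' @param grid_shape integer vector `c(rows, cols)`; the product is the number
#'   of lattice points J.
#' @param extent numeric vector of length 2 `c(lo, hi)` applied to both latent
#'   axes, or a 2x2 matrix with one row `c(lo, hi)` per axis. Default
#'   `c(-1, 1)`.
#' @return An object of class `gtm_grid`: a list with `points` (J x 2 matrix
#'   of latent coordinates), `shape`, and `extent` (2 x 2 matrix).
#' @examples
#' g <- make_grid(c(20, 20))
#' nrow(g$points)  # 400
#' @export
make_grid <- function(grid_shape, extent = c(-1, 1)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(is.na(grid_shape)) || any(grid_shape < 1L))
    stop("'grid_shape' must be two positive integers")
  extent <- extent_matrix(extent)
  ax1 <- axis_points(grid_shape[1L], extent[1L, ])
  ax2 <- axis_points(grid_shape[2L], extent[2L, ])
  # row-major: first axis varies slowest
  pts <- cbind(rep(ax1, each = grid_shape[2L]),
               rep(ax2, times = grid_shape[1L]))
  colnames(pts) <- c("r1", "r2")
  structure(list(points = pts, shape = grid_shape, extent = extent),
            class = "gtm_grid")
}

extent_matrix <- function(extent) {
  if (is.matrix(extent)) {
    if (!all(dim(extent) == c(2L, 2L))) stop("'extent' matrix must be 2 x 2")
  } else {
    if (length(extent) != 2L) stop("'extent' must be c(lo, hi) or a 2 x 2 matrix")
    extent <- matrix(extent, nrow = 2L, ncol = 2L, byrow = TRUE)
  }
  if (any(!is.finite(extent)) || any(extent[, 2L] <= extent[, 1L]))
    stop("'extent' must be finite with hi > lo on each axis")
  extent
}

axis_points <- function(n, range) {
  if (n == 1L) (range[1L] + range[2L]) / 2 else seq(range[1L], range[2L], length.out = n)
}

#' Build a radial Gaussian basis set over a lattice
#'
#' Places K Gaussian kernel centers on a regular sub-grid of the lattice
#' extent and sets a shared kernel width from the spacing between adjacent
#' centers: `sigma = width_factor * spacing` (the squared width `sigma2` is
#' stored). These kernels act as "attractors": they determine how strongly
#' nearby latent points pull on the same region of the data manifold.
#'
#' @param lattice a `gtm_grid`.
#' @param basis_shape integer vector `c(rows, cols)`; product is K.
#' @param width_factor positive multiplier on the inter-center spacing.
#' @param sigma2 optional explicit squared width, required when the basis has
#'   a single center (spacing is undefined).
#' @param has_bias add a constant basis column (default `FALSE`).
#' @return An object of class `gtm_basis`: list with `centers` (K x 2),
#'   `sigma2`, `has_bias`.
#' @examples
#' g <- make_grid(c(20, 20))
#' b <- make_basis(g, c(4, 4))
#' nrow(b$centers)  # 16
#' @export
make_basis <- function(lattice, basis_shape, width_factor = 1, sigma2 = NULL,
                       has_bias = FALSE) {
  stopifnot(inherits(lattice, "gtm_grid"))
  basis_shape <- as.integer(basis_shape)
  if (length(basis_shape) != 2L || any(is.na(basis_shape)) || any(basis_shape < 1L))
    stop("'basis_shape' must be two positive integers")
  if (!is.null(sigma2)) {
    if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0)
      stop("'sigma2' must be a positive scalar")
  } else {
    if (!is.numeric(width_factor) || length(width_factor) != 1L || width_factor <= 0)
      stop("'width_factor' must be positive")
  }
  ext <- lattice$extent
  ax1 <- axis_points(basis_shape[1L], ext[1L, ])
  ax2 <- axis_points(basis_shape[2L], ext[2L, ])
  centers <- cbind(rep(ax1, each = basis_shape[2L]),
                   rep(ax2, times = basis_shape[1L]))
  colnames(centers) <- c("r1", "r2")
  if (is.null(sigma2)) {
    spacings <- c(if (basis_shape[1L] > 1L) diff(ax1)[1L],
                  if (basis_shape[2L] > 1L) diff(ax2)[1L])
    if (length(spacings) == 0L)
      stop("a single-center basis needs an explicit 'sigma2'")
    sigma2 <- (width_factor * mean(spacings))^2
  }
  structure(list(centers = centers, sigma2 = sigma2, has_bias = isTRUE(has_bias)),
            class = "gtm_basis")
}

#' Evaluate the basis design matrix
#'
#' Evaluates every Gaussian kernel at every latent point:
#' `Phi[j, k] = exp(-||r_j - mu_k||^2 / (2 sigma^2))`. When the basis carries
#' a bias term a constant column of ones is appended.
#'
#' @param basis a `gtm_basis`.
#' @param lattice a `gtm_grid`, or a numeric matrix of latent points (rows).
#' @return J x K (or J x (K+1) with bias) numeric matrix with entries in
#'   (0, 1].
#' @export
design_matrix <- function(basis, lattice) {
  stopifnot(inherits(basis, "gtm_basis"))
  pts <- if (inherits(lattice, "gtm_grid")) lattice$points else as.matrix(lattice)
  Phi <- basis_eval(pts, basis$centers, basis$sigma2)
  if (basis$has_bias) Phi <- cbind(Phi, 1)
  Phi
}

# kernel evaluation at arbitrary latent points; pts J x q, centers K x q
basis_eval <- function(pts, centers, sigma2) {
  d2 <- sq_dist(pts, centers)
  exp(-d2 / (2 * sigma2))
}

# squared Euclidean distances between rows of A (n x q) and rows of B (m x q)
sq_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
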