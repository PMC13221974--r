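#' Quadrature grid on the unit sphere
#'
#' Builds a tensor-product quadrature grid for spherical-harmonics analysis up
#' to band limit `L`: Gauss--Legendre nodes in \eqn{\cos\theta} crossed with
#' uniformly spaced azimuthal angles. With `oversample_factor >= 1` the grid
#' integrates any product of two basis functions of degree at most `L`
#' exactly (to quadrature precision), which is what makes the forward
#' expansion by weighted summation an exact inverse of reconstruction for
#' band-limited fields.
#'
#' @param L Band limit (maximum spherical-harmonics degree), integer >= 0.
#' @param oversample_factor Multiplier on the minimal node counts; >= 1.
#'   The grid has `oversample_factor * (L + 1)` polar nodes and
#'   `oversample_factor * (2 * L + 2)` azimuthal nodes.
#'
#' @return A tibble of class `lira_grid` with one row per node and columns
#'   `theta` (polar angle, radians), `phi` (azimuth, radians) and `weight`
#'   (quadrature weight; weights sum to \eqn{4\pi}). Attributes `L`,
#'   `n_theta`, `n_phi` and `oversample_factor` record the construction.
#'
#' @examples
#' g <- make_grid(15)
#' sum(g$weight)  # 4 * pi
#' @export
make_grid <- function(L, oversample_factor = 2) {
  stopifnot(length(L) == 1, L >= 0, L == as.integer(L),
            length(oversample_factor) == 1, oversample_factor >= 1)
  n_theta <- as.integer(ceiling(oversample_factor * (L + 1)))
  n_phi   <- as.integer(ceiling(oversample_factor * (2 * L + 2)))

  if (n_theta == 1) {
    # one-point Gauss-Legendre rule on [-1, 1]
    x <- 0; wx <- 2
  } else {
    gl <- pracma::gaussLegendre(n_theta, -1, 1)
    # gaussLegendre returns nodes in ascending x = cos(theta)
    x  <- gl$x
    wx <- gl$w
  }
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi

  grid <- tidyr::expand_grid(
    theta = acos(x),
    phi   = phi
  )
  grid$weight <- rep(wx * (2 * pi / n_phi), each = n_phi)

  structure(
    tibble::new_tibble(grid, class = "lira_grid"),
    L = as.integer(L),
    n_theta = n_theta,
    n_phi = n_phi,
    oversample_factor = oversample_factor
  )
}

#' @export
print.lira_grid <- function(x, ...) {
  cat(sprintf("# Sphere quadrature grid: L = %d, %d x %d nodes\n",
              attr(x, "L"), attr(x, "n_theta"), attr(x, "n_phi")))
  NextMethod()
}

grid_L <- function(grid) {
  L <- attr(grid, "L")
  if (is.null(L)) stop("not a lira_grid: missing band-limit attribute", call. = FALSE)
  L
}

#' Unit direction vectors of grid nodes
#'
#' @param grid A `lira_grid` (or any data frame with `theta` and `phi`).
#' @return An n-by-3 matrix of unit vectors (x, y, z).
#' @keywords internal
#' @noRd
grid_directions <- function(grid) {
  st <- sin(grid$theta)
  cbind(st * cos(grid$phi), st * sin(grid$phi), cos(grid$theta))
}

#' Centre of geometry of a molecule
#'
#' Unweighted mean of the atomic positions; the origin of the star-shaped
#' radial surface parameterization.
#'
#' @param molecule A `lira_molecule` (tibble with `x`, `y`, `z` columns).
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
center_of_geometry <- function(molecule) {
  stopifnot(nrow(molecule) >= 1)
  c(mean(molecule$x), mean(molecule$y), mean(molecule$z))
}
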