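#' Normalized associated Legendre function
#'
#' Evaluates \eqn{\bar{P}_{\ell m}(x) = \sqrt{\frac{2\ell+1}{4\pi}
#' \frac{(\ell-m)!}{(\ell+m)!}} P_{\ell m}(x)} without the Condon--Shortley
#' phase, by the standard stable upward recursion in \eqn{\ell}. No factorials
#' are formed, so the evaluation is safe far beyond degree 64.
#'
#' @param l Degree, integer >= 0.
#' @param m Order, integer with 0 <= m <= l.
#' @param x Evaluation points in \[-1, 1\] (vectorized).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' legendre_norm(0, 0, 0.3)     # 1 / sqrt(4 * pi)
#' legendre_norm(1, 0, 1)       # sqrt(3 / (4 * pi))
#' @export
legendre_norm <- function(l, m, x) {
  stopifnot(length(l) == 1, length(m) == 1, m >= 0, m <= l)
  if (any(abs(x) > 1 + 1e-12)) stop("legendre_norm: |x| > 1", call. = FALSE)
  x <- pmin(1, pmax(-1, x))
  s <- sqrt(pmax(0, 1 - x^2))

  # P̄_mm by the diagonal recursion
  pmm <- rep(1 / sqrt(4 * pi), length(x))
  if (m > 0) {
    for (k in seq_len(m)) pmm <- pmm * sqrt((2 * k + 1) / (2 * k)) * s
  }
  if (l == m) return(pmm)

  pm1 <- x * sqrt(2 * m + 3) * pmm            # P̄_{m+1,m}
  if (l == m + 1) return(pm1)

  for (ll in (m + 2):l) {
    a <- sqrt((4 * ll^2 - 1) / (ll^2 - m^2))
    b <- sqrt(((ll - 1)^2 - m^2) / (4 * (ll - 1)^2 - 1))
    pnew <- a * (x * pm1 - b * pmm)
    pmm <- pm1
    pm1 <- pnew
  }
  pm1
}

#' Real spherical harmonic
#'
#' Orthonormal real spherical harmonics: \eqn{Y_{\ell 0} =
#' \bar{P}_{\ell 0}(\cos\theta)}; for \eqn{m > 0},
#' \eqn{Y_{\ell m} = \sqrt{2}\,\bar{P}_{\ell m}(\cos\theta)\cos(m\phi)} and
#' \eqn{Y_{\ell,-m} = \sqrt{2}\,\bar{P}_{\ell m}(\cos\theta)\sin(m\phi)}.
#' The \eqn{\sqrt{2}} factor makes the family orthonormal on the sphere,
#' which is the contract every expansion and fingerprint downstream relies on.
#'
#' @param l Degree, 0 <= l <= 64.
#' @param m Order, -l <= m <= l.
#' @param theta Polar angle(s), radians.
#' @param phi Azimuthal angle(s), radians.
#' @return Numeric vector.
#' @examples
#' real_sph_harm(0, 0, 1, 2)  # 1 / sqrt(4 * pi) everywhere
#' @export
real_sph_harm <- function(l, m, theta, phi) {
  stopifnot(length(l) == 1, length(m) == 1, l >= 0, l <= 64, abs(m) <= l)
  p <- legendre_norm(l, abs(m), cos(theta))
  if (m == 0) p
  else if (m > 0) sqrt(2) * p * cos(m * phi)
  else sqrt(2) * p * sin(abs(m) * phi)
}

# Flat index of (l, m) in the coefficient vector: degrees are stored
# l-major with m running from -l to l, so (l, m) -> l^2 + l + m + 1.
lm_index <- function(l, m) l^2 + l + m + 1

#' Basis matrix of real spherical harmonics on a set of points
#'
#' @param theta,phi Node angles (equal-length vectors).
#' @param L Band limit.
#' @return length(theta) x (L+1)^2 matrix; column `lm_index(l, m)` holds
#'   \eqn{Y_{\ell m}} at the nodes.
#' @keywords internal
#' @noRd
sh_basis <- function(theta, phi, L) {
  n <- length(theta)
  B <- matrix(0, n, (L + 1)^2)
  x <- cos(theta)
  for (m in 0:L) {
    if (m == 0) {
      for (l in 0:L) B[, lm_index(l, 0)] <- legendre_norm(l, 0, x)
    } else {
      cm <- sqrt(2) * cos(m * phi)
      sm <- sqrt(2) * sin(m * phi)
      for (l in m:L) {
        p <- legendre_norm(l, m, x)
        B[, lm_index(l,  m)] <- p * cm
        B[, lm_index(l, -m)] <- p * sm
      }
    }
  }
  B
}

# Basis matrices are reused heavily (every expansion / reconstruction on the
# same grid); cache them keyed on the grid geometry.
.basis_cache <- new.env(parent = emptyenv())

grid_basis <- function(grid, L) {
  key <- paste0("L", L, "_nt", attr(grid, "n_theta"), "_np", attr(grid, "n_phi"),
                "_", signif(sum(grid$theta), 15))
  B <- .basis_cache[[key]]
  if (is.null(B)) {
    B <- sh_basis(grid$theta, grid$phi, L)
    .basis_cache[[key]] <- B
  }
  B
}

#' Construct a coefficient set
#'
#' @param values Numeric vector of length (L+1)^2, ordered degree-major with
#'   order m from -l to l within each degree.
#' @param L Band limit.
#' @param channel `"shape"` (units Angstrom) or `"esp"`
#'   (kcal mol^-1 e^-1).
#' @return A `lira_coeffs` object.
#' @export
sh_coefficients <- function(values, L, channel = c("shape", "esp")) {
  channel <- match.arg(channel)
  stopifnot(length(values) == (L + 1)^2, all(is.finite(values)))
  structure(as.numeric(values), L = as.integer(L), channel = channel,
            class = "lira_coeffs")
}

#' @export
print.lira_coeffs <- function(x, ...) {
  cat(sprintf("# Spherical-harmonics coefficients: channel '%s', L = %d (%d values)\n",
              attr(x, "channel"), attr(x, "L"), length(x)))
  utils::str(unclass(x))
  invisible(x)
}

coeffs_L <- function(coeffs) attr(coeffs, "L")

#' Forward spherical-harmonics expansion by quadrature
#'
#' Computes \eqn{a_{\ell m} = \int_\Omega f\, Y_{\ell m}\, d\Omega} as a
#' weighted sum over the grid nodes. Exact (to quadrature precision) whenever
#' `values` is band-limited at degree <= L and the grid's band limit is >= L.
#'
#' @param values Field samples at the grid nodes (e.g. a `radius` or `esp`
#'   column of a surface field), or a surface-field tibble, in which case
#'   `channel` selects the column.
#' @param grid The `lira_grid` the values were sampled on.
#' @param L Band limit of the expansion; must not exceed the grid's.
#' @param channel `"shape"` or `"esp"`; selects the column when `values` is a
#'   data frame and labels the result.
#' @return A `lira_coeffs` vector of length (L+1)^2.
#' @examples
#' g <- make_grid(8)
#' a <- sh_expand(rep(2, nrow(g)), g, L = 8)
#' a[1]  # 2 * sqrt(4 * pi)
#' @export
sh_expand <- function(values, grid, L = grid_L(grid), channel = c("shape", "esp")) {
  channel <- match.arg(channel)
  if (is.data.frame(values)) {
    col <- if (channel == "shape") "radius" else "esp"
    values <- values[[col]]
  }
  if (L > grid_L(grid)) {
    stop("sh_expand: requested L exceeds the grid band limit", call. = FALSE)
  }
  stopifnot(length(values) == nrow(grid))
  B <- grid_basis(grid, L)
  a <- as.numeric(crossprod(B, grid$weight * values))
  sh_coefficients(a, L, channel)
}

#' Truncated reconstruction from coefficients
#'
#' Evaluates \eqn{f_L(\theta,\phi) = \sum_{\ell \le L} \sum_m a_{\ell m}
#' Y_{\ell m}(\theta,\phi)} at the grid nodes.
#'
#' @param coeffs A `lira_coeffs` object.
#' @param grid A `lira_grid` with band limit >= the coefficients' L.
#' @return Numeric vector of node values.
#' @export
sh_reconstruct <- function(coeffs, grid) {
  L <- coeffs_L(coeffs)
  B <- grid_basis(grid, L)
  as.numeric(B %*% as.numeric(coeffs))
}

#' Quadrature-weighted RMSD of the truncation residual
#'
#' \eqn{\sqrt{\sum w (f - f_L)^2 / \sum w}}: the root-mean-square deviation,
#' over the sphere, between the sampled field and its truncated
#' reconstruction, in the channel's units.
#'
#' @param values Field samples at the grid nodes (or a surface-field tibble;
#'   see [sh_expand()]).
#' @param coeffs Coefficients of the truncated expansion.
#' @param grid The sampling grid.
#' @param channel Column selector when `values` is a data frame.
#' @return Scalar RMSD.
#' @export
reconstruction_rmsd <- function(values, coeffs, grid, channel = c("shape", "esp")) {
  channel <- match.arg(channel)
  if (is.data.frame(values)) {
    col <- if (channel == "shape") "radius" else "esp"
    values <- values[[col]]
  }
  resid <- values - sh_reconstruct(coeffs, grid)
  sqrt(sum(grid$weight * resid^2) / sum(grid$weight))
}

#' Tidy a coefficient set
#'
#' @param x A `lira_coeffs` object.
#' @param ... Unused.
#' @return A tibble with columns `l`, `m`, `value`, `channel`.
#' @importFrom generics tidy
#' @export
tidy.lira_coeffs <- function(x, ...) {
  L <- coeffs_L(x)
  l <- rep(0:L, times = 2 * (0:L) + 1)
  m <- unlist(lapply(0:L, function(ll) -ll:ll))
  tibble::tibble(l = l, m = m, value = as.numeric(x),
                 channel = attr(x, "channel"))
}
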