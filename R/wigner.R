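# Wigner rotation machinery for real spherical-harmonics coefficients.
#
# Internally the rotation acts in the complex basis, where a ZYZ rotation
# factorizes as diagonal(exp(-i m alpha)) %*% d^l(beta) %*% diagonal(exp(-i m gamma)).
# The little-d matrix d^l(beta) = exp(-beta * K_l) is the matrix exponential of
# the real antisymmetric generator K_l = (J+ - J-)/2, evaluated through the
# eigendecomposition of K_l (computed once per degree and cached) so that
# d^l is orthogonal to machine precision at every beta.

.wigner_cache <- new.env(parent = emptyenv())

# Generator K_l = (J+ - J-)/2 in the |l, m> basis, m = -l..l.
wigner_generator <- function(l) {
  n <- 2 * l + 1
  K <- matrix(0, n, n)
  m <- -l:l
  if (l > 0) {
    for (i in seq_len(n - 1)) {
      cplus <- sqrt(l * (l + 1) - m[i] * (m[i] + 1)) / 2   # raises m -> m+1
      K[i + 1, i] <- cplus
      K[i, i + 1] <- -cplus
    }
  }
  K
}

wigner_eigen <- function(l) {
  key <- paste0("eig", l)
  e <- .wigner_cache[[key]]
  if (is.null(e)) {
    e <- eigen(wigner_generator(l))
    e$vinv <- solve(e$vectors)
    .wigner_cache[[key]] <- e
  }
  e
}

# Little-d matrix d^l(beta): real orthogonal (2l+1) x (2l+1).
wigner_d_beta <- function(l, beta) {
  if (l == 0) return(matrix(1, 1, 1))
  e <- wigner_eigen(l)
  Re(e$vectors %*% (exp(-beta * e$values) * e$vinv))
}

# Unitary change of basis U_l mapping real coefficient vectors to complex
# ones (c = U r): the real functions are S_{l,+m} = ((-1)^m Y_{lm} + Y_{l,-m}) / sqrt(2),
# S_{l,-m} = ((-1)^m Y_{lm} - Y_{l,-m}) / (i sqrt(2)), S_{l,0} = Y_{l,0},
# with Y the Condon--Shortley complex harmonics.
real_to_complex_basis <- function(l) {
  key <- paste0("U", l)
  U <- .wigner_cache[[key]]
  if (is.null(U)) {
    n <- 2 * l + 1
    U <- matrix(0i, n, n)
    idx <- function(m) m + l + 1   # position of order m
    U[idx(0), idx(0)] <- 1
    if (l > 0) {
      for (m in 1:l) {
        ph <- (-1)^m
        # complex coefficient row for order +m and -m in terms of the real
        # (cosine: +m, sine: -m) coefficients
        U[idx(m),  idx(m)]  <- ph / sqrt(2)
        U[idx(m),  idx(-m)] <- ph / (1i * sqrt(2))
        U[idx(-m), idx(m)]  <- 1 / sqrt(2)
        U[idx(-m), idx(-m)] <- -1 / (1i * sqrt(2))
      }
    }
    .wigner_cache[[key]] <- U
  }
  U
}

# Real Wigner-D block for one degree: coefficients of f(R^-1 x) are
# D_real %*% coefficients of f.
wigner_D_real <- function(l, alpha, beta, gamma) {
  if (l == 0) return(matrix(1, 1, 1))
  m <- -l:l
  d <- wigner_d_beta(l, beta)
  Dc <- (exp(-1i * m * alpha) * d) * rep(exp(-1i * m * gamma), each = 2 * l + 1)
  U <- real_to_complex_basis(l)
  Re(Conj(t(U)) %*% Dc %*% U)
}

#' Rotate a coefficient set with Wigner-D matrices
#'
#' Applies the degree-block real Wigner-D transform for the ZYZ Euler rotation
#' \eqn{R = R_z(\alpha) R_y(\beta) R_z(\gamma)}. The rotated coefficients are
#' exactly those of the rotated function: if `f` has coefficients `a`, the
#' function `x -> f(R^-1 x)` has coefficients `wigner_rotate(a, ...)`. The
#' per-degree norms (the rotation-invariant fingerprint) are preserved.
#'
#' @param coeffs A `lira_coeffs` object.
#' @param alpha,beta,gamma ZYZ Euler angles in radians (`beta` in \[0, pi\]).
#' @return A `lira_coeffs` object of the same band limit and channel.
#' @examples
#' g <- make_grid(4)
#' a <- sh_expand(1 + sin(g$theta) * cos(g$phi), g, 4)
#' b <- wigner_rotate(a, 0.3, 0.2, 0.1)
#' @export
wigner_rotate <- function(coeffs, alpha, beta, gamma) {
  L <- coeffs_L(coeffs)
  out <- as.numeric(coeffs)
  for (l in 0:L) {
    if (l == 0) next
    idx <- lm_index(l, -l):lm_index(l, l)
    out[idx] <- wigner_D_real(l, alpha, beta, gamma) %*% out[idx]
  }
  sh_coefficients(out, L, attr(coeffs, "channel"))
}

#' Euler angles to rotation matrix (ZYZ convention)
#'
#' @param alpha,beta,gamma Euler angles, radians.
#' @return 3x3 rotation matrix \eqn{R_z(\alpha) R_y(\beta) R_z(\gamma)}.
#' @export
euler_to_matrix <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Rotation matrix to ZYZ Euler angles
#'
#' Inverse of [euler_to_matrix()]; at the gimbal-degenerate poles
#' (`beta` = 0 or pi) the convention `gamma = 0` is used.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector `c(alpha, beta, gamma)` with `beta` in
#'   \[0, pi\] and `alpha`, `gamma` in \[0, 2 pi).
#' @export
matrix_to_euler <- function(R) {
  beta <- acos(pmin(1, pmax(-1, R[3, 3])))
  if (abs(sin(beta)) < 1e-10) {
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -alpha
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha = alpha %% (2 * pi), beta = beta, gamma = gamma %% (2 * pi))
}

# Geodesic distance (radians) between two rotations given as 3x3 matrices.
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}
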