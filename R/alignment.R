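# Rotational alignment by direct correlation over SO(3).
#
# The normalized coefficient correlation C(R) = sum_l a_l . (D^l(R) b_l) /
# (|a||b|) is evaluated on a (2B)^3 grid of ZYZ Euler angles. In the complex
# basis the rotation factorizes as exp(-i m' alpha) d^l(beta) exp(-i m gamma),
# so for each beta on the grid the correlation over the whole (alpha, gamma)
# plane collapses to two small complex matrix products — no SO(3) FFT is
# needed at the band limits used here.

so3_grid_angles <- function(B) {
  list(
    alpha = 2 * pi * (0:(2 * B - 1)) / (2 * B),
    beta  = pi * (2 * (0:(2 * B - 1)) + 1) / (4 * B),
    gamma = 2 * pi * (0:(2 * B - 1)) / (2 * B)
  )
}

# Complex per-degree coefficient blocks of a real coefficient vector.
complex_blocks <- function(coeffs) {
  L <- coeffs_L(coeffs)
  v <- as.numeric(coeffs)
  lapply(0:L, function(l) {
    idx <- lm_index(l, -l):lm_index(l, l)
    real_to_complex_basis(l) %*% v[idx]
  })
}

# Correlation (unnormalized) at a single rotation, from complex blocks.
so3_corr_single <- function(ca, cb, alpha, beta, gamma) {
  L <- length(ca) - 1
  acc <- 0
  for (l in 0:L) {
    m <- -l:l
    d <- wigner_d_beta(l, beta)
    rot <- (exp(-1i * m * alpha) * d) %*% (exp(-1i * m * gamma) * cb[[l + 1]])
    acc <- acc + Re(sum(Conj(ca[[l + 1]]) * rot))
  }
  acc
}

#' Maximize the rotational correlation of two coefficient sets
#'
#' Scans a \eqn{(2B)^3} ZYZ Euler-angle grid for the rotation maximizing the
#' normalized coefficient correlation, then polishes the best grid point with
#' derivative-free simplex descent. The returned rotation is the one that,
#' applied to `coeffs_mov` (equivalently to the moving molecule), best
#' matches `coeffs_ref`.
#'
#' @param coeffs_ref,coeffs_mov `lira_coeffs` of the same band limit.
#' @param grid_resolution Bandwidth `B` of the rotation grid (default
#'   `L + 1`).
#' @param refine Polish the best grid rotation with Nelder--Mead.
#' @return List with `alpha`, `beta`, `gamma` (radians), `rotation` (3x3
#'   matrix), `correlation` (in \[-1, 1\]) and `degenerate` (`TRUE` when the
#'   correlation landscape is flat near its maximum, as for a pure sphere or
#'   a symmetric molecule; the first maximizer in lexicographic Euler order
#'   is then kept).
#' @export
so3_correlation <- function(coeffs_ref, coeffs_mov,
                            grid_resolution = coeffs_L(coeffs_ref) + 1,
                            refine = TRUE) {
  L <- coeffs_L(coeffs_ref)
  if (coeffs_L(coeffs_mov) != L) {
    stop("so3_correlation: band limits differ", call. = FALSE)
  }
  na <- sqrt(sum(as.numeric(coeffs_ref)^2))
  nb <- sqrt(sum(as.numeric(coeffs_mov)^2))
  if (na < 1e-14 || nb < 1e-14) {
    stop("so3_correlation: zero-norm coefficient set", call. = FALSE)
  }
  ca <- complex_blocks(coeffs_ref)
  cb <- complex_blocks(coeffs_mov)
  B <- as.integer(grid_resolution)
  ang <- so3_grid_angles(B)
  nm <- 2 * L + 1
  midx <- function(m) m + L + 1
  # Fourier factors over the alpha and gamma grids
  Fa <- exp(-1i * outer(ang$alpha, -L:L))       # (2B) x (2L+1)
  Fg <- exp(-1i * outer(ang$gamma, -L:L))
  best <- -Inf; best_idx <- c(1L, 1L, 1L)
  all_near <- 0L
  corr_vals <- numeric(0)
  for (k in seq_along(ang$beta)) {
    Tm <- matrix(0i, nm, nm)
    for (l in 0:L) {
      d <- wigner_d_beta(l, ang$beta[k])
      sub <- midx(-l:l)
      Tm[sub, sub] <- Tm[sub, sub] + Conj(ca[[l + 1]]) %*% t(cb[[l + 1]]) * d
    }
    Ck <- Re(Fa %*% Tm %*% t(Fg)) / (na * nb)   # (2B) x (2B): alpha x gamma
    mx <- max(Ck)
    corr_vals <- c(corr_vals, as.numeric(Ck))
    if (mx > best) {
      best <- mx
      ij <- which(Ck == mx, arr.ind = TRUE)[1, ]
      best_idx <- c(ij[1], k, ij[2])
    }
  }
  # flat-landscape (symmetry) detection: top grid values indistinguishable
  top <- sort(corr_vals, decreasing = TRUE)[seq_len(min(10, length(corr_vals)))]
  degenerate <- (top[1] - top[length(top)]) < 1e-6
  par <- c(ang$alpha[best_idx[1]], ang$beta[best_idx[2]], ang$gamma[best_idx[3]])
  corr <- best
  if (refine && !degenerate) {
    negC <- function(p) -so3_corr_single(ca, cb, p[1], p[2], p[3]) / (na * nb)
    opt <- stats::optim(par, negC, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 400))
    if (-opt$value >= corr) {
      par <- opt$par
      corr <- -opt$value
    }
  }
  list(alpha = par[1] %% (2 * pi), beta = par[2], gamma = par[3] %% (2 * pi),
       rotation = euler_to_matrix(par[1], par[2], par[3]),
       correlation = corr, degenerate = degenerate)
}

#' Apply a rigid transform to a molecule
#'
#' Maps every coordinate as `x -> R x + translation`; all other fields and
#' attributes are preserved.
#'
#' @param molecule A `lira_molecule`.
#' @param rotation 3x3 rotation matrix, or length-3 ZYZ Euler angles.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed molecule.
#' @export
apply_transform <- function(molecule, rotation, translation = c(0, 0, 0)) {
  R <- if (is.matrix(rotation)) rotation
       else euler_to_matrix(rotation[1], rotation[2], rotation[3])
  xyz <- coords(molecule) %*% t(R)
  xyz <- sweep(xyz, 2, translation, `+`)
  set_coords(molecule, xyz)
}

#' Align one molecule onto another (ICP over surface expansions)
#'
#' Alternates between (1) expanding both star-shaped surfaces about their
#' centres of geometry, (2) finding the rotation maximizing the coefficient
#' correlation over SO(3), and (3) applying that rotation to the moving
#' molecule and re-expanding — until the correlation gain drops below `tol`
#' or `max_iter` is reached. The final transform maps the moving molecule's
#' original frame onto the reference frame (rotation about the mover's
#' centre, then translation of that centre onto the reference centre).
#'
#' @param mol_ref,mol_mov Molecules with radii assigned (charges too if
#'   `esp_weight > 0`).
#' @param L Band limit for the alignment expansions.
#' @param probe_radius,oversample_factor Surface build parameters.
#' @param esp_weight Weight of the ESP-channel correlation in the joint
#'   objective (0 = shape only).
#' @param tol Convergence threshold on the correlation improvement.
#' @param max_iter Iteration cap; exceeding it returns `converged = FALSE`
#'   rather than an error.
#' @param grid_resolution Rotation-grid bandwidth (see [so3_correlation()]).
#' @return A `lira_alignment`: list with `rotation` (3x3), `euler`,
#'   `translation`, `correlation`, `iterations`, `converged`, `degenerate`
#'   and `molecule` (the transformed mover).
#' @export
icp_align <- function(mol_ref, mol_mov, L = 15, probe_radius = 1.4,
                      oversample_factor = 2, esp_weight = 0,
                      tol = 1e-4, max_iter = 10,
                      grid_resolution = L + 1) {
  grid <- make_grid(L, oversample_factor)
  c_ref <- center_of_geometry(mol_ref)
  a <- expand_for_alignment(mol_ref, grid, L, probe_radius, esp_weight)
  c_mov0 <- center_of_geometry(mol_mov)
  mov <- mol_mov
  R_acc <- diag(3)
  corr_prev <- -Inf
  corr <- NA_real_
  degenerate <- FALSE
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    b <- expand_for_alignment(mov, grid, L, probe_radius, esp_weight)
    fit <- so3_correlation(a, b, grid_resolution)
    if (fit$correlation >= 1 - tol) {
      # already an (essentially) perfect match: accept and stop
      corr <- fit$correlation
      degenerate <- degenerate || fit$degenerate
      converged <- TRUE
      iters <- it
      mov <- rotate_about(mov, fit$rotation)
      R_acc <- fit$rotation %*% R_acc
      break
    }
    if (fit$correlation <= corr_prev + tol) {
      corr <- max(corr_prev, fit$correlation)
      degenerate <- degenerate || fit$degenerate
      converged <- TRUE
      iters <- it
      if (fit$correlation > corr_prev) {
        mov <- rotate_about(mov, fit$rotation)
        R_acc <- fit$rotation %*% R_acc
      }
      break
    }
    corr_prev <- fit$correlation
    corr <- fit$correlation
    degenerate <- degenerate || fit$degenerate
    mov <- rotate_about(mov, fit$rotation)
    R_acc <- fit$rotation %*% R_acc
    iters <- it
    if (it == max_iter) converged <- FALSE
  }
  translation <- c_ref - as.numeric(R_acc %*% c_mov0)
  aligned <- apply_transform(mol_mov, R_acc, translation)
  structure(list(
    rotation = R_acc, euler = matrix_to_euler(R_acc),
    translation = translation, correlation = corr,
    iterations = iters, converged = converged, degenerate = degenerate,
    molecule = aligned
  ), class = "lira_alignment")
}

# Rotate a molecule about its own centre of geometry.
rotate_about <- function(m, R) {
  c0 <- center_of_geometry(m)
  apply_transform(m, R, c0 - as.numeric(R %*% c0))
}

# Surface expansion used by the alignment objective; with esp_weight > 0 the
# two channels are stacked (each normalized) into one coefficient vector so
# the joint correlation uses the same weighting as the combined score.
expand_for_alignment <- function(m, grid, L, probe_radius, esp_weight) {
  field <- radial_surface(m, grid, probe_radius)
  a <- sh_expand(field, grid, L, channel = "shape")
  if (esp_weight <= 0) return(a)
  field <- sample_esp(m, field)
  e <- sh_expand(field, grid, L, channel = "esp")
  na <- sqrt(sum(as.numeric(a)^2)); ne <- sqrt(sum(as.numeric(e)^2))
  v <- (1 - esp_weight) * as.numeric(a) / max(na, 1e-12) +
    esp_weight * as.numeric(e) / max(ne, 1e-12)
  # stacking as a weighted sum keeps the per-degree block structure intact
  sh_coefficients(v, L, "shape")
}

#' @export
print.lira_alignment <- function(x, ...) {
  cat(sprintf(
    "# Alignment: correlation %.4f after %d iteration(s)%s%s\n  euler (deg): %.1f %.1f %.1f; translation (A): %.2f %.2f %.2f\n",
    x$correlation, x$iterations,
    if (x$converged) ", converged" else ", NOT converged",
    if (x$degenerate) " [degenerate landscape]" else "",
    x$euler[1] * 180 / pi, x$euler[2] * 180 / pi, x$euler[3] * 180 / pi,
    x$translation[1], x$translation[2], x$translation[3]
  ))
  invisible(x)
}

#' Tidy an alignment result
#'
#' @param x A `lira_alignment`.
#' @param ... Unused.
#' @return One-row tibble with the Euler angles, translation components and
#'   fit diagnostics.
#' @export
tidy.lira_alignment <- function(x, ...) {
  tibble::tibble(
    alpha = x$euler[["alpha"]], beta = x$euler[["beta"]],
    gamma = x$euler[["gamma"]],
    tx = x$translation[1], ty = x$translation[2], tz = x$translation[3],
    correlation = x$correlation, iterations = x$iterations,
    converged = x$converged, degenerate = x$degenerate
  )
}

#' @export
glance.lira_alignment <- function(x, ...) {
  tibble::tibble(correlation = x$correlation, iterations = x$iterations,
                 converged = x$converged, degenerate = x$degenerate)
}

#' Write an alignment transform as a JSON sidecar
#'
#' @param alignment A `lira_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_json <- function(alignment, path) {
  jsonlite::write_json(
    list(alpha = alignment$euler[["alpha"]], beta = alignment$euler[["beta"]],
         gamma = alignment$euler[["gamma"]],
         translation = alignment$translation,
         correlation = alignment$correlation,
         converged = alignment$converged),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
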