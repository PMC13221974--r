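# Star-shaped radial surface sampling.
#
# The surface is the outer envelope of the union of atom spheres (vdW radius
# + probe). Along each grid direction u from the centre of geometry, the
# retained crossing is the FARTHEST ray-sphere intersection over all atoms:
# t_i = d_i.u + sqrt(R_i^2 - rho_i^2) for atoms whose perpendicular distance
# rho_i <= R_i, with d_i the atom offset from the centre and R_i = r_i + probe.
# Rays that hit no sphere are filled by a fallback and flagged.

#' Coulomb constant in kcal A mol^-1 e^-2
#' @keywords internal
#' @noRd
COULOMB_K <- 332.0636

#' Sample the star-shaped radial surface of a molecule
#'
#' For every quadrature node direction, records the distance from the
#' molecular centre of geometry to the outer envelope of the atom spheres
#' (van der Waals radius plus `probe_radius`). Nodes whose ray misses every
#' sphere are filled with the distance from the centre to the nearest
#' atom-sphere surface and flagged in `miss`; a miss fraction above
#' `miss_fraction_threshold` is an error (the star-shaped assumption has
#' broken down for that conformer).
#'
#' @param molecule A `lira_molecule` with radii assigned.
#' @param grid A `lira_grid` from [make_grid()].
#' @param probe_radius Solvent probe radius added to every atomic radius
#'   (Angstrom); 1.4 approximates a water-accessible envelope, 0 gives the
#'   bare vdW surface.
#' @param miss_fraction_threshold Hard-error threshold on the fraction of
#'   rays that miss all atom spheres.
#' @return A `lira_surface` tibble: the grid columns plus `radius`
#'   (Angstrom), `esp` (`NA` until [sample_esp()]) and `miss`. Attributes
#'   carry the centre, probe radius and grid geometry, so the field can be
#'   passed directly to [sh_expand()].
#' @export
radial_surface <- function(molecule, grid, probe_radius = 1.4,
                           miss_fraction_threshold = 0.05) {
  m <- molecule
  if (any(is.na(m$radius))) {
    stop("radial_surface: molecule has unset radii; call assign_radii() first",
         call. = FALSE)
  }
  stopifnot(probe_radius >= 0)
  center <- center_of_geometry(m)
  U <- grid_directions(grid)                       # n x 3 unit vectors
  D <- sweep(coords(m), 2, center)                 # nA x 3 atom offsets
  R <- m$radius + probe_radius
  proj <- U %*% t(D)                               # n x nA: d_i . u
  d2 <- rep(rowSums(D^2), each = nrow(U))
  disc <- matrix(rep(R^2, each = nrow(U)), nrow(U)) - (d2 - proj^2)
  t_far <- proj + sqrt(pmax(disc, 0))
  t_far[disc < 0] <- -Inf
  t_far[t_far <= 0] <- -Inf
  radius <- apply(t_far, 1, max)
  miss <- !is.finite(radius)
  if (all(miss)) {
    stop("radial_surface: every ray misses the molecular envelope; ",
         "is the centre of geometry outside the molecule?", call. = FALSE)
  }
  if (any(miss)) {
    fallback <- min(abs(sqrt(rowSums(D^2)) - R))
    radius[miss] <- fallback
    frac <- mean(miss)
    if (frac > miss_fraction_threshold) {
      stop(sprintf(paste0("radial_surface: %.1f%% of rays miss the atom spheres ",
                          "(threshold %.1f%%); the star-shaped assumption fails ",
                          "for this conformer"),
                   100 * frac, 100 * miss_fraction_threshold), call. = FALSE)
    }
    warning(sprintf("radial_surface: %.2f%% of rays missed the atom spheres; ",
                    100 * frac), "filled with nearest-surface distance",
            call. = FALSE)
  }
  out <- tibble::tibble(
    theta = grid$theta, phi = grid$phi, weight = grid$weight,
    radius = radius, esp = NA_real_, miss = miss
  )
  structure(
    tibble::new_tibble(out, class = c("lira_surface", "lira_grid")),
    L = attr(grid, "L"), n_theta = attr(grid, "n_theta"),
    n_phi = attr(grid, "n_phi"),
    oversample_factor = attr(grid, "oversample_factor"),
    center = center, probe_radius = probe_radius,
    molecule_id = mol_id(m)
  )
}

#' @export
print.lira_surface <- function(x, ...) {
  cat(sprintf(
    "# Star-shaped surface of '%s': %d nodes, probe %.2f A, mean radius %.3f A%s\n",
    attr(x, "molecule_id") %||% "?", nrow(x), attr(x, "probe_radius"),
    mean(x$radius),
    if (any(x$miss)) sprintf(", %.2f%% ray misses", 100 * mean(x$miss)) else ""
  ))
  NextMethod()
}

#' Sample the electrostatic potential on the surface
#'
#' Evaluates a point-charge Coulomb potential at every surface point:
#' \eqn{V = k \sum_i q_i / |x - x_i|} with
#' \eqn{k = 332.0636} kcal A mol^-1 e^-2 (`"vacuum"`), or with the distance
#' squared in the denominator for the distance-dependent dielectric model.
#'
#' @param molecule The molecule the surface was built from, charges assigned.
#' @param surface_field A `lira_surface` from [radial_surface()].
#' @param dielectric_model `"vacuum"` or `"distance_dependent"`.
#' @return The surface field with its `esp` column populated
#'   (kcal mol^-1 e^-1).
#' @export
sample_esp <- function(molecule, surface_field,
                       dielectric_model = c("vacuum", "distance_dependent")) {
  dielectric_model <- match.arg(dielectric_model)
  m <- molecule
  if (any(is.na(m$charge))) {
    stop("sample_esp: molecule has unset charges; call assign_charges() first",
         call. = FALSE)
  }
  center <- attr(surface_field, "center")
  U <- grid_directions(surface_field)
  pts <- sweep(U * surface_field$radius, 2, center, `+`)   # n x 3 surface points
  esp <- numeric(nrow(pts))
  X <- coords(m)
  # n x nA distance matrix in blocks to bound memory on large grids
  d2 <- outer(rowSums(pts^2), rowSums(X^2), `+`) - 2 * pts %*% t(X)
  dist <- sqrt(pmax(d2, 0))
  if (any(dist < 1e-6)) {
    stop("sample_esp: surface point coincides with an atom centre", call. = FALSE)
  }
  denom <- if (dielectric_model == "vacuum") dist else dist^2
  esp <- COULOMB_K * as.numeric((1 / denom) %*% m$charge)
  surface_field$esp <- esp
  attr(surface_field, "dielectric_model") <- dielectric_model
  surface_field
}

#' Write a surface field as a tabular debug dump
#'
#' @param surface_field A `lira_surface`.
#' @param path Output path (TSV: theta, phi, weight, radius, esp, miss).
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface_field, path) {
  utils::write.table(as.data.frame(surface_field), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
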