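# Deterministic synthetic fixtures: analytic fields with closed-form
# expansions, band-limited random fields, random-walk molecules and decoy
# libraries. Everything is reproducible from its seed; analytic fields
# bypass the molecular surface path entirely, which isolates the harmonics
# core in oracle tests.

#' Spherical surface field (analytic fixture)
#'
#' Constant radius field: band-limited at degree 0, with
#' \eqn{a_{00} = r\sqrt{4\pi}} and zero reconstruction error at any L.
#'
#' @param radius Sphere radius (Angstrom), > 0.
#' @param grid A `lira_grid`.
#' @return A `lira_surface` with `radius` constant and `esp` zero.
#' @export
make_sphere_field <- function(radius, grid) {
  stopifnot(radius > 0)
  analytic_field(rep(radius, nrow(grid)), grid, "sphere")
}

#' Ellipsoidal star-shaped field (analytic fixture)
#'
#' Radial function of the axis-aligned ellipsoid with semi-axes `a`, `b`,
#' `c`: \eqn{r(\theta,\phi) = (\sin^2\theta\cos^2\phi/a^2 +
#' \sin^2\theta\sin^2\phi/b^2 + \cos^2\theta/c^2)^{-1/2}}. Permuting the
#' semi-axes rotates the shape, so the rotation-invariant fingerprints of
#' (2,1,1) and (1,2,1) coincide.
#'
#' @param a,b,c Semi-axes (Angstrom), > 0.
#' @param grid A `lira_grid`.
#' @return A `lira_surface`.
#' @export
make_ellipsoid_field <- function(a, b, c, grid) {
  stopifnot(a > 0, b > 0, c > 0)
  st <- sin(grid$theta)
  r <- 1 / sqrt((st * cos(grid$phi))^2 / a^2 +
                (st * sin(grid$phi))^2 / b^2 +
                cos(grid$theta)^2 / c^2)
  analytic_field(r, grid, "ellipsoid")
}

analytic_field <- function(r, grid, id) {
  out <- tibble::tibble(theta = grid$theta, phi = grid$phi,
                        weight = grid$weight, radius = r,
                        esp = 0, miss = FALSE)
  structure(
    tibble::new_tibble(out, class = c("lira_surface", "lira_grid")),
    L = attr(grid, "L"), n_theta = attr(grid, "n_theta"),
    n_phi = attr(grid, "n_phi"),
    oversample_factor = attr(grid, "oversample_factor"),
    center = c(0, 0, 0), probe_radius = 0, molecule_id = id
  )
}

#' Band-limited random field with known coefficients
#'
#' Draws coefficients from a zero-mean normal with per-degree scale
#' `decay^l`, reconstructs the field on the grid, and (when used as a radius
#' channel) shifts the monopole so the field stays positive. The returned
#' pair is the round-trip oracle: expanding the field must recover the drawn
#' coefficients exactly.
#'
#' @param L Band limit of the drawn coefficients (<= the grid's).
#' @param decay Per-degree amplitude decay in (0, 1\]; 0 keeps only l = 0.
#' @param seed Integer seed; identical seeds give identical output.
#' @param grid A `lira_grid`.
#' @param positive Shift the monopole so all field values are >= 0.1.
#' @return List with `coeffs` (`lira_coeffs`) and `field` (`lira_surface`
#'   with the values in `radius`).
#' @export
make_bandlimited <- function(L, decay, seed, grid, positive = TRUE) {
  stopifnot(L <= grid_L(grid))
  rng <- local_rng(seed)
  sd_l <- decay^rep(0:L, times = 2 * (0:L) + 1)
  v <- rng$rnorm((L + 1)^2) * sd_l
  if (decay == 0) v[-1] <- 0
  a <- sh_coefficients(v, L)
  f <- sh_reconstruct(a, grid)
  if (positive) {
    lo <- min(f)
    if (lo < 0.1) {
      shift <- 0.1 - lo
      v[1] <- v[1] + shift * sqrt(4 * pi)
      a <- sh_coefficients(v, L)
      f <- f + shift
    }
  }
  list(coeffs = a, field = analytic_field(f, grid, sprintf("bandlimited_s%d", seed)))
}

#' Seeded random-walk molecule
#'
#' A self-avoiding random walk with 1.5-Angstrom steps; radii sampled from
#' {1.2, 1.5, 1.7} Angstrom (labelled H/N/C so the SDF round trip is
#' element-consistent), charges drawn then shifted to exact net zero, and
#' chain bonds between consecutive atoms. Not chemically realistic — it is
#' a geometry/e-statics fixture, not a molecule model.
#'
#' @param n_atoms Number of atoms, >= 1.
#' @param seed Integer seed.
#' @param id Conformer identifier.
#' @param compound_id Parent-compound identifier.
#' @return A `lira_molecule` with radii and charges populated.
#' @export
make_synthetic_molecule <- function(n_atoms, seed, id = sprintf("synmol_s%d", seed),
                                    compound_id = id) {
  stopifnot(n_atoms >= 1)
  rng <- local_rng(seed)
  pos <- matrix(0, n_atoms, 3)
  if (n_atoms > 1) {
    for (i in 2:n_atoms) {
      repeat {
        step <- rng$rnorm(3)
        step <- 1.5 * step / sqrt(sum(step^2))
        cand <- pos[i - 1, ] + step
        d <- sqrt(rowSums(sweep(pos[seq_len(i - 2), , drop = FALSE], 2, cand)^2))
        if (i == 2 || all(d > 1.2)) break
      }
      pos[i, ] <- cand
    }
  }
  radius_set <- c(H = 1.2, N = 1.5, C = 1.7)
  pick <- 1 + floor(rng$runif(n_atoms) * 3)
  q <- rng$rnorm(n_atoms, sd = 0.1)
  q <- q - mean(q)
  bonds <- if (n_atoms > 1) {
    tibble::tibble(a1 = 1:(n_atoms - 1), a2 = 2:n_atoms, order = 1L)
  } else NULL
  molecule(
    tibble::tibble(element = names(radius_set)[pick],
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   radius = unname(radius_set[pick]), charge = q),
    id = id, compound_id = compound_id, bonds = bonds
  )
}

#' Write a decoy screening library
#'
#' A multi-record SDF of seeded synthetic molecules named
#' `CPD<k>_conf<j>`; conformers of one compound are rigid random rotations
#' of its base geometry. Optionally plants one extra compound that is a
#' Gaussian-jittered copy of a supplied query, for retrieval experiments.
#'
#' @param n_compounds,conformers_each Library dimensions.
#' @param seed Integer seed.
#' @param out_sdf Output SDF path.
#' @param n_atoms Atoms per synthetic molecule.
#' @param planted_query Optional `lira_molecule` to plant.
#' @param jitter_sd Coordinate jitter (Angstrom) applied to the planted copy.
#' @return `out_sdf`, invisibly; the planted conformer is named
#'   `PLANTED_conf1`.
#' @export
make_decoy_library <- function(n_compounds, conformers_each, seed, out_sdf,
                               n_atoms = 12, planted_query = NULL,
                               jitter_sd = 0.05) {
  stopifnot(n_compounds >= 1, conformers_each >= 1)
  rng <- local_rng(seed)
  mols <- list()
  for (k in seq_len(n_compounds)) {
    base <- make_synthetic_molecule(n_atoms, seed = seed + 1000L + k)
    for (j in seq_len(conformers_each)) {
      m <- base
      if (j > 1) {
        ang <- c(rng$runif(1, 0, 2 * pi), rng$runif(1, 0, pi),
                 rng$runif(1, 0, 2 * pi))
        m <- rotate_about(m, euler_to_matrix(ang[1], ang[2], ang[3]))
      }
      cid <- sprintf("CPD%04d", k)
      m <- set_mol_attr(m, "id", sprintf("%s_conf%d", cid, j))
      m <- set_mol_attr(m, "compound_id", cid)
      mols[[length(mols) + 1]] <- m
    }
  }
  if (!is.null(planted_query)) {
    q <- planted_query
    xyz <- coords(q) + matrix(rng$rnorm(3 * nrow(q), sd = jitter_sd), ncol = 3)
    q <- set_coords(q, xyz)
    q <- set_mol_attr(q, "id", "PLANTED_conf1")
    q <- set_mol_attr(q, "compound_id", "PLANTED")
    mols[[length(mols) + 1]] <- q
  }
  write_sdf(mols, out_sdf)
  invisible(out_sdf)
}

#' Committed drug-like conformer set
#'
#' Twenty drug-like small molecules with explicit hydrogens and fixed 3D
#' coordinates (one conformer each, generated once with a distance-geometry
#' embedding followed by MMFF94s minimization and committed as static data,
#' so results never depend on toolkit version drift). Used for the
#' surface-fidelity benchmarks.
#'
#' @return List of `lira_molecule` objects (radii/charges unset).
#' @export
druglike_set <- function() {
  path <- system.file("extdata", "druglike_set.sdf", package = "liraseek")
  read_sdf(path)
}

# Self-contained RNG: all fixture randomness flows through one seeded
# generator per call, without touching the session's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(rnorm = with_state(stats::rnorm), runif = with_state(stats::runif))
}
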