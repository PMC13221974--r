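test_that("centre of geometry is the unweighted mean of atom positions", {
  expect_equal(center_of_geometry(single_atom(c(1, 2, 3))), c(1, 2, 3))
  two <- molecule(data.frame(element = c("C", "C"), x = c(1, -1),
                             y = c(0, 0), z = c(0, 0)))
  expect_equal(center_of_geometry(two), c(0, 0, 0))
  expect_equal(center_of_geometry(methane()), c(0, 0, 0), tolerance = 1e-6)
})

test_that("single-sphere surfaces reproduce the atomic radius plus probe", {
  m <- single_atom(radius = 1.7)
  f0 <- radial_surface(m, grid8, probe_radius = 0)
  expect_equal(f0$radius, rep(1.7, nrow(grid8)), tolerance = 1e-12)
  expect_false(any(f0$miss))
  f14 <- radial_surface(m, grid8, probe_radius = 1.4)
  expect_equal(f14$radius, rep(3.1, nrow(grid8)), tolerance = 1e-12)
})

test_that("two-sphere far intersection matches the closed form and a root search", {
  two <- molecule(data.frame(element = c("C", "C"), x = c(1, -1), y = c(0, 0),
                             z = c(0, 0), radius = 1, charge = 0))
  g <- make_grid(8, 2)
  f <- radial_surface(two, g, probe_radius = 0)
  # along +x the far crossing of the sphere at (1,0,0) is t = 1 + 1 = 2
  ray <- function(u) {
    tt <- seq(0.01, 4, by = 1e-5)
    pts <- outer(tt, u)
    inside <- sqrt(rowSums(sweep(pts, 2, c(1, 0, 0))^2)) <= 1 |
      sqrt(rowSums(sweep(pts, 2, c(-1, 0, 0))^2)) <= 1
    max(tt[inside])
  }
  # compare the analytic construction against dense numeric root search on
  # a few node directions
  U <- liraseek:::grid_directions(g)
  set.seed(7)
  # avoid near-tangent rays (|u_x| ~ 0), where the brute-force search and the
  # closed form are both ill-conditioned
  eligible <- which(abs(U[, 1]) > 0.3)
  for (i in sample(eligible, 5)) {
    expect_equal(f$radius[i], ray(U[i, ]), tolerance = 1e-4)
  }
  node_px <- which.max(U[, 1])  # direction closest to +x
  expect_equal(f$radius[node_px], 2, tolerance = 0.02)
})

test_that("ray misses are filled, warned about, and bounded by the threshold", {
  # two small distant spheres leave most rays with no intersection
  far <- molecule(data.frame(element = c("C", "C"), x = c(5, -5), y = c(0, 0),
                             z = c(0, 0), radius = 0.8, charge = 0))
  expect_error(radial_surface(far, grid8, probe_radius = 0,
                              miss_fraction_threshold = 0.05), "star-shaped")
  expect_warning(
    f <- radial_surface(far, grid8, probe_radius = 0, miss_fraction_threshold = 1),
    "missed"
  )
  expect_true(any(f$miss))
  expect_true(all(f$radius > 0))
  # fallback value is the distance from the centre to the nearest sphere surface
  expect_equal(unique(f$radius[f$miss]), 5 - 0.8, tolerance = 1e-12)
})

test_that("surface sampling is translation invariant and radius-monotone", {
  m <- assign_radii(methane())
  f1 <- radial_surface(m, grid8, 1.4)
  shifted <- liraseek:::set_coords(m, liraseek:::coords(m) +
                                     matrix(rep(c(10, -4, 2), each = 5), ncol = 3))
  f2 <- radial_surface(shifted, grid8, 1.4)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-9)

  # inflating every atomic radius inflates the surface everywhere
  bigger <- m
  bigger$radius <- m$radius + 0.3
  f3 <- radial_surface(bigger, grid8, 1.4)
  expect_true(all(f3$radius >= f1$radius - 1e-12))
  expect_gt(mean(f3$radius), mean(f1$radius))
})

test_that("grid-aligned azimuthal rotation permutes the sampled values exactly", {
  m <- assign_radii(methane())
  n_phi <- attr(grid8, "n_phi")
  dphi <- 2 * pi / n_phi
  rot <- liraseek:::rotate_about(m, euler_to_matrix(dphi, 0, 0))
  f <- radial_surface(m, grid8, 1.4)
  frot <- radial_surface(rot, grid8, 1.4)
  # value at phi node j of the rotated molecule = value at node j-1 originally
  v <- matrix(f$radius, ncol = n_phi, byrow = TRUE)
  vr <- matrix(frot$radius, ncol = n_phi, byrow = TRUE)
  expect_equal(vr[, c(2:n_phi, 1)], v, tolerance = 1e-9)
})

test_that("Coulomb ESP matches closed forms on spherical surfaces", {
  m <- single_atom(radius = 2, charge = 1)
  f <- radial_surface(m, grid8, probe_radius = 0)
  f <- sample_esp(m, f)
  expect_equal(f$esp, rep(332.0636 / 2, nrow(grid8)), tolerance = 1e-9)

  # distance-dependent dielectric divides by r^2
  f2 <- sample_esp(m, radial_surface(m, grid8, 0), "distance_dependent")
  expect_equal(f2$esp, rep(332.0636 / 4, nrow(grid8)), tolerance = 1e-9)

  z <- assign_charges(assign_radii(methane()), "zero")
  fz <- sample_esp(z, radial_surface(z, grid8, 1.4))
  expect_identical(unique(fz$esp), 0)
})

test_that("dipole ESP is antisymmetric and vanishes on the mirror plane", {
  dip <- molecule(data.frame(element = c("C", "C"), x = c(0.5, -0.5),
                             y = c(0, 0), z = c(0, 0), radius = 2,
                             charge = c(1, -1)))
  f <- sample_esp(dip, radial_surface(dip, grid8, 0))
  U <- liraseek:::grid_directions(grid8)
  # nodes come in (phi -> pi - phi) pairs with mirrored x; compare via
  # explicit reflected evaluation instead of node pairing
  pts <- U * f$radius
  refl <- cbind(-pts[, 1], pts[, 2], pts[, 3])
  esp_at <- function(p) {
    d1 <- sqrt(rowSums(sweep(p, 2, c(0.5, 0, 0))^2))
    d2 <- sqrt(rowSums(sweep(p, 2, c(-0.5, 0, 0))^2))
    332.0636 * (1 / d1 - 1 / d2)
  }
  expect_equal(esp_at(refl), -f$esp, tolerance = 1e-9)
  on_plane <- abs(pts[, 1]) < 1e-10
  if (any(on_plane)) expect_lt(max(abs(f$esp[on_plane])), 1e-9)
})

test_that("ESP sampling requires charges and rejects coincident points", {
  m <- assign_radii(methane())
  f <- radial_surface(m, grid8, 1.4)
  expect_error(sample_esp(m, f), "unset charges")
})
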