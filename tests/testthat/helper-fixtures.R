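# Shared fixtures for the suite. Grids are cheap to build but reused a lot.

grid8 <- make_grid(8, 2)
grid15 <- make_grid(15, 2)

# Tetrahedral methane with explicit bonds; C-H 1.089 A.
methane <- function() {
  s <- 1.089 / sqrt(3)
  molecule(
    data.frame(
      element = c("C", "H", "H", "H", "H"),
      x = c(0, s, -s, -s, s),
      y = c(0, s, -s, s, -s),
      z = c(0, s, s, -s, -s)
    ),
    id = "methane", bonds = data.frame(a1 = 1, a2 = 2:5, order = 1)
  )
}

# One-atom molecule at a given position.
single_atom <- function(pos = c(0, 0, 0), element = "C", radius = NA_real_,
                        charge = NA_real_) {
  molecule(data.frame(element = element, x = pos[1], y = pos[2], z = pos[3],
                      radius = radius, charge = charge), id = "atom")
}

atom_rmsd <- function(a, b) {
  sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
}

random_euler <- function() {
  c(runif(1, 0, 2 * pi), runif(1, 0.05, pi - 0.05), runif(1, 0, 2 * pi))
}
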