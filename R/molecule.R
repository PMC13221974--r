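#' Construct a molecule
#'
#' A molecule is a tibble with one row per atom (columns `element`, `x`, `y`,
#' `z` in Angstrom, `radius` in Angstrom, `charge` in elementary charges;
#' `radius`/`charge` may be `NA` until assigned) and attributes carrying the
#' conformer identity, the parent-compound identity, SDF data tags and, when
#' the source format provides it, the bond list (used for Gasteiger charge
#' assignment and preserved through SDF round trips).
#'
#' @param atoms Data frame with at least `element`, `x`, `y`, `z`; optional
#'   `radius` and `charge`.
#' @param id Conformer identifier.
#' @param compound_id Parent-compound identifier (defaults to `id`).
#' @param properties Named character vector of SDF data tags.
#' @param bonds Optional data frame with columns `a1`, `a2`, `order`
#'   (1-based atom indices).
#' @return A `lira_molecule` tibble.
#' @export
molecule <- function(atoms, id = "mol", compound_id = id,
                     properties = character(), bonds = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("molecule: non-finite coordinates", call. = FALSE)
  }
  if (any(!is.na(atoms$radius) & atoms$radius <= 0)) {
    stop("molecule: atomic radii must be positive", call. = FALSE)
  }
  atoms <- tibble::as_tibble(atoms[, c("element", "x", "y", "z", "radius", "charge")])
  structure(
    tibble::new_tibble(atoms, class = "lira_molecule"),
    id = id, compound_id = compound_id,
    properties = properties, bonds = bonds
  )
}

#' @export
print.lira_molecule <- function(x, ...) {
  cat(sprintf("# Molecule '%s' (compound '%s'): %d atoms%s\n",
              attr(x, "id"), attr(x, "compound_id"), nrow(x),
              if (!is.null(attr(x, "bonds"))) sprintf(", %d bonds", nrow(attr(x, "bonds"))) else ""))
  NextMethod()
}

mol_id <- function(m) attr(m, "id")
mol_compound_id <- function(m) attr(m, "compound_id")
mol_properties <- function(m) attr(m, "properties") %||% character()
mol_bonds <- function(m) attr(m, "bonds")

set_mol_attr <- function(m, which, value) {
  attr(m, which) <- value
  m
}

# Replace coordinates, keeping every other field and attribute.
set_coords <- function(m, xyz) {
  m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
  m
}

coords <- function(m) cbind(m$x, m$y, m$z)

`%||%` <- function(a, b) if (is.null(a)) b else a
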