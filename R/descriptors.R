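#' Rotation-invariant fingerprint of a coefficient set
#'
#' The per-degree amplitudes \eqn{A_\ell = (\sum_m a_{\ell m}^2)^{1/2}} and the
#' total amplitude \eqn{A_L = (\sum_\ell A_\ell^2)^{1/2}}. Because each degree
#' block transforms under rotation by an orthogonal Wigner-D matrix, the
#' amplitude vector is exactly invariant under any rigid rotation of the
#' molecule — which is what lets the screening stage rank without aligning.
#'
#' @param coeffs A `lira_coeffs` object.
#' @return A `lira_rif` tibble with columns `l` and `amplitude`; attributes
#'   `total`, `channel`, `L`.
#' @examples
#' g <- make_grid(6)
#' rif(sh_expand(rep(2, nrow(g)), g, 6))  # A0 = 2 * sqrt(4 * pi), rest 0
#' @export
rif <- function(coeffs) {
  L <- coeffs_L(coeffs)
  v <- as.numeric(coeffs)
  amp <- vapply(0:L, function(l) sqrt(sum(v[(l^2 + 1):((l + 1)^2)]^2)), 0)
  structure(
    tibble::new_tibble(tibble::tibble(l = 0:L, amplitude = amp),
                       class = "lira_rif"),
    total = sqrt(sum(amp^2)), channel = attr(coeffs, "channel"), L = L
  )
}

#' @export
print.lira_rif <- function(x, ...) {
  cat(sprintf("# Rotation-invariant fingerprint: channel '%s', L = %d, total %.4f\n",
              attr(x, "channel"), attr(x, "L"), attr(x, "total")))
  NextMethod()
}

rif_total <- function(r) attr(r, "total")

#' DRIF distance between two fingerprints
#'
#' \eqn{\mathrm{DRIF}^2 = A_L^2 + B_L^2 - 2\sum_\ell A_\ell B_\ell}, i.e. the
#' squared Euclidean distance between the two amplitude vectors. The square
#' root is returned by default so the value is a true metric in the channel's
#' units; set `squared = TRUE` for the raw quadratic form.
#'
#' @param rif_a,rif_b `lira_rif` fingerprints of the same channel and band
#'   limit.
#' @param squared Return the squared distance instead of the distance.
#' @return Scalar distance (>= 0; 0 iff the amplitude vectors coincide).
#' @export
drif <- function(rif_a, rif_b, squared = FALSE) {
  if (attr(rif_a, "L") != attr(rif_b, "L")) {
    stop("drif: fingerprints have different band limits", call. = FALSE)
  }
  d2 <- sum((rif_a$amplitude - rif_b$amplitude)^2)
  if (squared) d2 else sqrt(d2)
}

#' Combined shape + electrostatics ranking score
#'
#' Dimensionless weighted sum of the per-channel DRIF distances, each
#' normalized by the query's total amplitude in that channel:
#' `shape_weight * DRIF_shape / A_L(shape) + (1 - shape_weight) * DRIF_esp /
#' max(A_L(esp), eps)`. The epsilon guards neutral (zero-ESP) queries.
#'
#' @param query_desc,hit_desc `lira_descriptor` objects (see
#'   [describe_molecule()]).
#' @param shape_weight Weight of the shape channel in \[0, 1\]; 1 ranks by
#'   shape alone.
#' @param eps Floor on the ESP normalization amplitude.
#' @return Scalar score (>= 0; 0 for identical descriptors).
#' @export
combined_score <- function(query_desc, hit_desc, shape_weight = 0.5,
                           eps = 1e-8) {
  stopifnot(shape_weight >= 0, shape_weight <= 1)
  ds <- drif(query_desc$shape_rif, hit_desc$shape_rif)
  s <- shape_weight * ds / max(rif_total(query_desc$shape_rif), eps)
  if (shape_weight < 1) {
    if (is.null(query_desc$esp_rif) || is.null(hit_desc$esp_rif)) {
      stop("combined_score: ESP channel requested (shape_weight < 1) but a ",
           "descriptor has no ESP fingerprint", call. = FALSE)
    }
    de <- drif(query_desc$esp_rif, hit_desc$esp_rif)
    s <- s + (1 - shape_weight) * de / max(rif_total(query_desc$esp_rif), eps)
  }
  s
}

#' Compute the two-channel descriptor of a molecule
#'
#' The full per-conformer pipeline: assign radii and charges (when missing),
#' sample the star-shaped surface and its Coulomb ESP, expand both channels
#' at band limit `L`, and reduce to rotation-invariant fingerprints.
#'
#' @param molecule A `lira_molecule`.
#' @param L Band limit (15 by default; 6 is a fast preset that remains
#'   adequate for ranking).
#' @param probe_radius Solvent probe added to atomic radii (Angstrom).
#' @param oversample_factor Quadrature oversampling (see [make_grid()]).
#' @param charge_method Charge model for the ESP channel (see
#'   [assign_charges()]); `"zero"` gives a shape-only descriptor with a null
#'   ESP fingerprint.
#' @param radius_table Radius-set name for [assign_radii()].
#' @param dielectric_model ESP dielectric model (see [sample_esp()]).
#' @param grid Optional prebuilt grid (reused across a library scan).
#' @param keep_coefficients Keep the full coefficient vectors in the result
#'   (needed later only for alignment output).
#' @return A `lira_descriptor`: list with `conformer_id`, `compound_id`,
#'   `shape_rif`, `esp_rif`, `L`, and optionally `shape_coeffs`/`esp_coeffs`.
#' @export
describe_molecule <- function(molecule, L = 15, probe_radius = 1.4,
                              oversample_factor = 2,
                              charge_method = c("gasteiger", "file", "zero"),
                              radius_table = "bondi",
                              dielectric_model = "vacuum",
                              grid = NULL, keep_coefficients = FALSE) {
  charge_method <- match.arg(charge_method)
  m <- molecule
  if (any(is.na(m$radius))) m <- assign_radii(m, radius_table)
  if (any(is.na(m$charge)) || charge_method != "file") {
    m <- assign_charges(m, charge_method)
  }
  if (is.null(grid)) grid <- make_grid(L, oversample_factor)
  field <- radial_surface(m, grid, probe_radius)
  field <- sample_esp(m, field, dielectric_model)
  a_shape <- sh_expand(field, grid, L, channel = "shape")
  a_esp <- sh_expand(field, grid, L, channel = "esp")
  out <- list(
    conformer_id = mol_id(m), compound_id = mol_compound_id(m),
    shape_rif = rif(a_shape), esp_rif = rif(a_esp), L = L
  )
  if (keep_coefficients) {
    out$shape_coeffs <- a_shape
    out$esp_coeffs <- a_esp
  }
  structure(out, class = "lira_descriptor")
}

#' @export
print.lira_descriptor <- function(x, ...) {
  cat(sprintf("# Descriptor of '%s' (compound '%s'), L = %d\n",
              x$conformer_id, x$compound_id, x$L))
  cat(sprintf("  shape total %.4f A; esp total %.4f kcal/mol/e\n",
              rif_total(x$shape_rif),
              if (!is.null(x$esp_rif)) rif_total(x$esp_rif) else NA))
  invisible(x)
}

#' Tidy a descriptor into a long amplitude table
#'
#' @param x A `lira_descriptor`.
#' @param ... Unused.
#' @return Tibble with columns `conformer_id`, `compound_id`, `channel`, `l`,
#'   `amplitude`.
#' @export
tidy.lira_descriptor <- function(x, ...) {
  chans <- list(shape = x$shape_rif, esp = x$esp_rif)
  chans <- chans[!vapply(chans, is.null, TRUE)]
  purrr::map_dfr(names(chans), function(ch) {
    tibble::tibble(conformer_id = x$conformer_id, compound_id = x$compound_id,
                   channel = ch, l = chans[[ch]]$l,
                   amplitude = chans[[ch]]$amplitude)
  })
}

#' Dump coefficients as JSON
#'
#' The flat order is part of the contract: degree-major, order m from -l to
#' l within each degree.
#'
#' @param coeffs A `lira_coeffs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coeffs_json <- function(coeffs, path) {
  jsonlite::write_json(
    list(channel = attr(coeffs, "channel"), L = coeffs_L(coeffs),
         order = "l-major, m from -l to l",
         values = as.numeric(coeffs)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
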