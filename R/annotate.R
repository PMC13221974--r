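#' Assign van der Waals radii from a named table
#'
#' Sets each atom's radius from a two-column element/radius table shipped with
#' the package (default: Bondi). Idempotent: reassigning with the same table
#' is a no-op. A table dropped into the package's `extdata` directory as
#' `radii_<name>.txt` becomes available under `<name>`.
#'
#' @param molecule A `lira_molecule`.
#' @param table Radius-set name; `"bondi"` is shipped.
#' @return The molecule with `radius` populated (Angstrom).
#' @examples
#' m <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
#' assign_radii(m)$radius  # 1.70
#' @export
assign_radii <- function(molecule, table = "bondi") {
  tab <- load_radius_table(table)
  elem <- normalize_element(molecule$element)
  r <- tab[elem]
  if (any(is.na(r))) {
    bad <- sort(unique(elem[is.na(r)]))
    stop("assign_radii: element(s) not in radius table '", table, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  molecule$radius <- unname(r)
  molecule
}

load_radius_table <- function(table) {
  path <- system.file("extdata", paste0("radii_", table, ".txt"),
                      package = "liraseek")
  if (!nzchar(path)) stop("assign_radii: unknown radius table '", table, "'",
                          call. = FALSE)
  df <- utils::read.table(path, col.names = c("element", "radius"),
                          comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(df$radius, normalize_element(df$element))
}

#' Assign partial charges
#'
#' Three charge models:
#' * `"gasteiger"` — Gasteiger--Marsili empirical charges computed by Open
#'   Babel from the molecule's connectivity (so the molecule must come from a
#'   bond-carrying format such as SDF);
#' * `"file"` — keep charges already present (PQR input);
#' * `"zero"` — all charges exactly zero (shape-only mode; the surface ESP
#'   is then identically zero).
#'
#' The total charge is recorded in the molecule's properties.
#'
#' @param molecule A `lira_molecule`.
#' @param method One of `"gasteiger"`, `"file"`, `"zero"`.
#' @return The molecule with `charge` populated.
#' @export
assign_charges <- function(molecule, method = c("gasteiger", "file", "zero")) {
  method <- match.arg(method)
  m <- molecule
  if (method == "zero") {
    m$charge <- 0
  } else if (method == "file") {
    if (any(is.na(m$charge))) {
      stop("assign_charges(method = 'file'): molecule carries no charges; ",
           "read it from PQR or choose another method", call. = FALSE)
    }
  } else {
    if (is.null(mol_bonds(m))) {
      stop("assign_charges(method = 'gasteiger'): molecule has no connectivity ",
           "(PDB input?); supply an SDF, or provide charges via PQR input ",
           "with method = 'file'", call. = FALSE)
    }
    m$charge <- gasteiger_charges(m)
  }
  props <- mol_properties(m)
  props["total_charge"] <- format(sum(m$charge), digits = 15)
  props["charge_method"] <- method
  set_mol_attr(m, "properties", props)
}

# Gasteiger-Marsili charges through the obabel CLI (SDF in, MOL2 out); atom
# order is preserved by Open Babel, so charges map back positionally.
gasteiger_charges <- function(m) {
  if (!nzchar(Sys.which("obabel"))) {
    stop("assign_charges: 'obabel' not found on PATH (Open Babel is required ",
         "for Gasteiger charges)", call. = FALSE)
  }
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(tmp_in, tmp_out)))
  write_sdf(m, tmp_in)
  status <- suppressWarnings(system2(
    "obabel", c(tmp_in, "-O", tmp_out, "--partialcharge", "gasteiger"),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0 || !file.exists(tmp_out)) {
    stop("assign_charges: obabel failed on molecule '", mol_id(m), "'",
         call. = FALSE)
  }
  lines <- readLines(tmp_out, warn = FALSE)
  beg <- grep("^@<TRIPOS>ATOM", lines)
  end <- grep("^@<TRIPOS>BOND", lines)
  if (length(beg) == 0) stop("assign_charges: malformed obabel output", call. = FALSE)
  end <- if (length(end) == 0) length(lines) + 1 else end[1]
  at <- lines[(beg[1] + 1):(end - 1)]
  at <- at[nzchar(trimws(at))]
  if (length(at) != nrow(m)) {
    stop("assign_charges: obabel returned ", length(at), " atoms for a ",
         nrow(m), "-atom molecule", call. = FALSE)
  }
  vapply(strsplit(trimws(at), "\\s+"),
         function(t) as.numeric(t[length(t)]), 0)
}

#' Add explicit hydrogens with Open Babel
#'
#' Hydrogens are never added implicitly anywhere in the pipeline; this helper
#' is the one explicit opt-in (surface volume depends on their presence).
#'
#' @param molecule A bond-carrying `lira_molecule`.
#' @return The molecule with explicit hydrogens appended.
#' @export
add_hydrogens <- function(molecule) {
  if (!nzchar(Sys.which("obabel"))) {
    stop("add_hydrogens: 'obabel' not found on PATH", call. = FALSE)
  }
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)))
  write_sdf(molecule, tmp_in)
  status <- suppressWarnings(system2("obabel", c(tmp_in, "-O", tmp_out, "-h"),
                                     stdout = FALSE, stderr = FALSE))
  if (status != 0) stop("add_hydrogens: obabel failed", call. = FALSE)
  out <- read_sdf(tmp_out)[[1]]
  out <- set_mol_attr(out, "id", mol_id(molecule))
  set_mol_attr(out, "compound_id", mol_compound_id(molecule))
}
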