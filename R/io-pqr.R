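#' Read a PQR file
#'
#' Whitespace-delimited PQR: ATOM/HETATM records whose final two numeric
#' fields are the partial charge (e) and radius (Angstrom). Charges and radii
#' are taken from the file verbatim; nothing is reassigned.
#'
#' @param path Path to the PQR file.
#' @param id Conformer identifier (default: file name without extension).
#' @return A `lira_molecule` with `charge` and `radius` populated.
#' @export
read_pqr <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM|HETATM)", lines)
  if (!any(sel)) stop("read_pqr: no atoms in '", path, "'", call. = FALSE)
  rows <- which(sel)
  parse_one <- function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # ATOM serial name resName [chain] resSeq x y z q r
    if (length(tok) < 10) {
      stop("read_pqr: line ", i, " is truncated (expected at least 10 fields, got ",
           length(tok), ")", call. = FALSE)
    }
    n <- length(tok)
    vals <- suppressWarnings(as.numeric(tok[(n - 4):n]))
    if (any(is.na(vals))) {
      stop("read_pqr: line ", i, " has non-numeric coordinate/charge/radius fields",
           call. = FALSE)
    }
    name <- tok[3]
    elem <- normalize_element(gsub("[^A-Za-z].*$", "", name))
    c(list(element = elem), as.list(vals))
  }
  parsed <- lapply(rows, parse_one)
  atoms <- tibble::tibble(
    element = vapply(parsed, function(p) p$element, ""),
    x = vapply(parsed, function(p) p[[2]], 0),
    y = vapply(parsed, function(p) p[[3]], 0),
    z = vapply(parsed, function(p) p[[4]], 0),
    charge = vapply(parsed, function(p) p[[5]], 0),
    radius = vapply(parsed, function(p) p[[6]], 0)
  )
  m <- molecule(atoms, id = id)
  props <- mol_properties(m)
  props["total_charge"] <- format(sum(atoms$charge), digits = 15)
  props["charge_method"] <- "file"
  set_mol_attr(m, "properties", props)
}

#' Write a molecule as PQR
#'
#' @param molecule A `lira_molecule` with radii and charges assigned.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(molecule, path) {
  m <- molecule
  if (any(is.na(m$charge))) stop("write_pqr: molecule has unset charges", call. = FALSE)
  if (any(is.na(m$radius))) stop("write_pqr: molecule has unset radii", call. = FALSE)
  name <- make_atom_names(m$element)
  lines <- sprintf("ATOM %6d %-4s LIG %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
                   seq_len(nrow(m)), name, 1L, m$x, m$y, m$z, m$charge, m$radius)
  writeLines(lines, path)
  invisible(path)
}
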