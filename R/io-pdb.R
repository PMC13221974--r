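#' Read a PDB file (ATOM/HETATM subset)
#'
#' Reads coordinates from fixed-column ATOM and HETATM records. Radii and
#' charges are left unset; assign them with [assign_radii()] and
#' [assign_charges()]. When alternate locations are present, only the first
#' altloc code encountered is kept, with a warning.
#'
#' @param path Path to the PDB file.
#' @param id Conformer identifier for the resulting molecule (default: file
#'   name without extension).
#' @return A `lira_molecule` (radii and charges `NA`).
#' @export
read_pdb <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("read_pdb: no atoms in '", path, "'", call. = FALSE)
  altloc <- substr(rec, 17, 17)
  if (any(altloc != " ")) {
    keep_code <- setdiff(unique(altloc), " ")[1]
    drop <- altloc != " " & altloc != keep_code
    if (any(drop)) {
      warning("read_pdb: dropping ", sum(drop),
              " alternate-location atoms (keeping altloc '", keep_code, "')",
              call. = FALSE)
      rec <- rec[!drop]
    }
  }
  elem <- trimws(substr(rec, 77, 78))
  name <- trimws(substr(rec, 13, 16))
  fallback <- gsub("[^A-Za-z].*$", "", name)
  elem[!nzchar(elem)] <- fallback[!nzchar(elem)]
  elem <- normalize_element(elem)
  atoms <- tibble::tibble(
    element = elem,
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54))
  )
  molecule(atoms, id = id)
}

#' Write a molecule as PDB HETATM records
#'
#' @param molecule A `lira_molecule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(molecule, path) {
  m <- molecule
  name <- make_atom_names(m$element)
  lines <- sprintf(
    "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(m)), name, m$x, m$y, m$z, toupper(m$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# First-letter-capitalized element symbols ("CL" -> "Cl").
normalize_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

make_atom_names <- function(elements) {
  counts <- stats::ave(seq_along(elements), elements, FUN = seq_along)
  paste0(toupper(elements), counts)
}
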