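#' Read an SDF file
#'
#' Parses a multi-record SDF (V2000 read/write; V3000 read) into a list of
#' molecules, preserving atom order, SDF data tags and the bond block.
#'
#' @param path Path to the SDF file.
#' @param compound_tag SDF data tag to take the parent-compound identifier
#'   from. `NULL` (default) uses the molecule title with any trailing
#'   `_confN` conformer suffix stripped.
#' @return List of `lira_molecule` objects, in file order.
#' @export
read_sdf <- function(path, compound_tag = NULL) {
  lines <- readLines(path, warn = FALSE)
  # split on record delimiters
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0 && length(trimws(lines)) > 0 && any(nzchar(trimws(lines)))) {
    ends <- length(lines)  # single record without terminator
  }
  if (length(ends) == 0) stop("read_sdf: no records in '", path, "'", call. = FALSE)
  starts <- c(1, utils::head(ends, -1) + 1)
  mols <- list()
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:ends[k]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (all(!nzchar(trimws(rec)))) next
    mols[[length(mols) + 1]] <- parse_sdf_record(rec, compound_tag)
  }
  if (length(mols) == 0) stop("read_sdf: no records in '", path, "'", call. = FALSE)
  mols
}

parse_sdf_record <- function(rec, compound_tag = NULL) {
  title <- trimws(rec[1])
  counts <- rec[4]
  v3000 <- grepl("V3000", counts)
  if (v3000) {
    parsed <- parse_v3000_block(rec)
  } else {
    n_atoms <- as.integer(substr(counts, 1, 3))
    n_bonds <- as.integer(substr(counts, 4, 6))
    if (is.na(n_atoms) || n_atoms < 1) stop("read_sdf: bad counts line", call. = FALSE)
    at <- rec[5:(4 + n_atoms)]
    atoms <- tibble::tibble(
      element = trimws(substr(at, 32, 34)),
      x = as.numeric(substr(at, 1, 10)),
      y = as.numeric(substr(at, 11, 20)),
      z = as.numeric(substr(at, 21, 30))
    )
    bonds <- NULL
    if (!is.na(n_bonds) && n_bonds > 0) {
      bl <- rec[(5 + n_atoms):(4 + n_atoms + n_bonds)]
      bonds <- tibble::tibble(
        a1 = as.integer(substr(bl, 1, 3)),
        a2 = as.integer(substr(bl, 4, 6)),
        order = as.integer(substr(bl, 7, 9))
      )
    }
    parsed <- list(atoms = atoms, bonds = bonds)
  }
  props <- parse_sdf_tags(rec)
  if (all(abs(parsed$atoms$z) < 1e-12)) {
    warning("read_sdf: all z coordinates are zero in record '", title,
            "': 2D structure suspected", call. = FALSE)
  }
  id <- if (nzchar(title)) title else "unnamed"
  cid <- if (!is.null(compound_tag) && compound_tag %in% names(props)) {
    props[[compound_tag]]
  } else {
    sub("_conf\\d+$", "", id)
  }
  molecule(parsed$atoms, id = id, compound_id = cid,
           properties = props, bonds = parsed$bonds)
}

parse_v3000_block <- function(rec) {
  grab <- function(tag_beg, tag_end) {
    i <- grep(tag_beg, rec, fixed = TRUE)
    j <- grep(tag_end, rec, fixed = TRUE)
    if (length(i) == 0) return(character())
    rec[(i[1] + 1):(j[1] - 1)]
  }
  at <- grab("M  V30 BEGIN ATOM", "M  V30 END ATOM")
  if (length(at) == 0) stop("read_sdf: V3000 record without atom block", call. = FALSE)
  tok <- strsplit(trimws(sub("^M  V30 ", "", at)), "\\s+")
  atoms <- tibble::tibble(
    element = vapply(tok, function(t) t[2], ""),
    x = vapply(tok, function(t) as.numeric(t[3]), 0),
    y = vapply(tok, function(t) as.numeric(t[4]), 0),
    z = vapply(tok, function(t) as.numeric(t[5]), 0)
  )
  bd <- grab("M  V30 BEGIN BOND", "M  V30 END BOND")
  bonds <- NULL
  if (length(bd) > 0) {
    tk <- strsplit(trimws(sub("^M  V30 ", "", bd)), "\\s+")
    bonds <- tibble::tibble(
      a1 = vapply(tk, function(t) as.integer(t[3]), 1L),
      a2 = vapply(tk, function(t) as.integer(t[4]), 1L),
      order = vapply(tk, function(t) as.integer(t[2]), 1L)
    )
  }
  list(atoms = atoms, bonds = bonds)
}

parse_sdf_tags <- function(rec) {
  idx <- grep("^>\\s*<", rec)
  props <- character()
  for (i in idx) {
    tag <- sub("^>\\s*<([^>]+)>.*$", "\\1", rec[i])
    vals <- character()
    j <- i + 1
    while (j <= length(rec) && nzchar(trimws(rec[j]))) {
      vals <- c(vals, rec[j])
      j <- j + 1
    }
    props[tag] <- paste(vals, collapse = "\n")
  }
  props
}

#' Write molecules to an SDF file (V2000)
#'
#' @param molecules A `lira_molecule` or list of them. An empty list writes an
#'   empty file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(molecules, path) {
  if (inherits(molecules, "lira_molecule")) molecules <- list(molecules)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in molecules) {
    writeLines(sdf_record_lines(m), con)
  }
  invisible(path)
}

sdf_record_lines <- function(m) {
  bonds <- mol_bonds(m)
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  out <- c(
    mol_id(m),
    "  liraseek",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(m), nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            m$x, m$y, m$z, m$element)
  )
  if (nb > 0) {
    out <- c(out, sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, bonds$order))
  }
  out <- c(out, "M  END")
  props <- mol_properties(m)
  for (tag in names(props)) {
    out <- c(out, sprintf(">  <%s>", tag), props[[tag]], "")
  }
  c(out, "$$$$")
}
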