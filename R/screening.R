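#' Build a descriptor database from a multi-conformer SDF library
#'
#' Computes the two-channel descriptor of every readable conformer and writes
#' them to a single-file database. Records that fail (unknown elements,
#' degenerate geometry, charge-assignment failures) are skipped with a
#' warning naming the conformer; the returned handle reports how many
#' succeeded. Output is deterministic for fixed inputs and parameters.
#'
#' @param library_sdf Path to the multi-record SDF library.
#' @param out_path Output database path.
#' @param L Band limit.
#' @param probe_radius,oversample_factor,charge_method,radius_table,dielectric_model
#'   Descriptor build parameters (see [describe_molecule()]).
#' @param compound_tag SDF tag carrying the parent-compound id (see
#'   [read_sdf()]).
#' @return A `lira_db` handle.
#' @export
build_db <- function(library_sdf, out_path, L = 15, probe_radius = 1.4,
                     oversample_factor = 2,
                     charge_method = c("gasteiger", "file", "zero"),
                     radius_table = "bondi", dielectric_model = "vacuum",
                     compound_tag = NULL) {
  charge_method <- match.arg(charge_method)
  mols <- read_sdf(library_sdf, compound_tag = compound_tag)
  grid <- make_grid(L, oversample_factor)
  n_failed <- 0L
  descs <- list()
  for (m in mols) {
    d <- tryCatch(
      describe_molecule(m, L = L, probe_radius = probe_radius,
                        oversample_factor = oversample_factor,
                        charge_method = charge_method,
                        radius_table = radius_table,
                        dielectric_model = dielectric_model, grid = grid),
      error = function(e) {
        warning("build_db: skipping conformer '", mol_id(m), "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (!is.null(d)) descs[[length(descs) + 1]] <- d else n_failed <- n_failed + 1L
  }
  if (length(descs) == 0) {
    stop("build_db: no conformer could be processed", call. = FALSE)
  }
  if (n_failed > 0) {
    message("build_db: ", length(descs), " records written, ", n_failed,
            " skipped")
  }
  params <- list(L = as.integer(L), probe_radius = probe_radius,
                 charge_method = charge_method,
                 oversample_factor = oversample_factor,
                 radius_table = radius_table,
                 dielectric_model = dielectric_model)
  write_descriptor_db(descs, out_path, params)
}

#' Rank a descriptor database against a query molecule
#'
#' Linear scan: the query is processed with the database's own build
#' parameters (a stored parameter fingerprint prevents silent mismatches),
#' the combined shape + ESP score is computed against every record, and the
#' hits are sorted ascending with deterministic tie-breaking by
#' (compound_id, conformer_id). At most `per_compound_cap` conformers per
#' compound are retained before the top `n` cut.
#'
#' @param db A `lira_db` or a database path.
#' @param query A `lira_molecule`, or a precomputed `lira_descriptor` (whose
#'   band limit must match the database's).
#' @param n Number of hits to return.
#' @param shape_weight Shape-channel weight of [combined_score()].
#' @param per_compound_cap Maximum conformers reported per compound.
#' @return A `lira_hits` tibble: `rank`, `compound_id`, `conformer_id`,
#'   `drif_shape`, `drif_esp`, `score`; attributes record the query and scan
#'   parameters.
#' @export
query_db <- function(db, query, n = 50, shape_weight = 0.5,
                     per_compound_cap = 5) {
  if (is.character(db)) db <- read_descriptor_db(db)
  p <- db$params
  qd <- if (inherits(query, "lira_descriptor")) {
    if (query$L != p$L) {
      stop("query_db: query descriptor L = ", query$L,
           " does not match database L = ", p$L, call. = FALSE)
    }
    query
  } else {
    describe_molecule(query, L = p$L, probe_radius = p$probe_radius,
                      oversample_factor = p$oversample_factor,
                      charge_method = p$charge_method,
                      radius_table = p$radius_table,
                      dielectric_model = p$dielectric_model)
  }
  qs <- qd$shape_rif$amplitude
  qe <- qd$esp_rif$amplitude
  ns <- max(rif_total(qd$shape_rif), 1e-8)
  ne <- max(rif_total(qd$esp_rif), 1e-8)
  recs <- db$records
  ds <- vapply(recs$shape_amplitudes, function(a) sqrt(sum((a - qs)^2)), 0)
  de <- vapply(recs$esp_amplitudes, function(a) sqrt(sum((a - qe)^2)), 0)
  score <- shape_weight * ds / ns + (1 - shape_weight) * de / ne
  hits <- tibble::tibble(
    compound_id = recs$compound_id, conformer_id = recs$conformer_id,
    drif_shape = ds, drif_esp = de, score = score
  )
  hits <- dplyr::arrange(hits, .data$score, .data$compound_id, .data$conformer_id)
  hits <- dplyr::slice_head(dplyr::group_by(hits, .data$compound_id),
                            n = per_compound_cap)
  hits <- dplyr::arrange(dplyr::ungroup(hits),
                         .data$score, .data$compound_id, .data$conformer_id)
  hits <- dplyr::slice_head(hits, n = n)
  hits$rank <- seq_len(nrow(hits))
  hits <- hits[, c("rank", "compound_id", "conformer_id",
                   "drif_shape", "drif_esp", "score")]
  structure(
    tibble::new_tibble(hits, class = "lira_hits"),
    query_id = qd$conformer_id, shape_weight = shape_weight,
    per_compound_cap = per_compound_cap, params = p
  )
}

#' @export
print.lira_hits <- function(x, ...) {
  cat(sprintf("# Hit list for query '%s': %d hits (shape weight %.2f, cap %d/compound)\n",
              attr(x, "query_id"), nrow(x), attr(x, "shape_weight"),
              attr(x, "per_compound_cap")))
  NextMethod()
}

#' Export ranked hits as SDF, PQR and a score report
#'
#' Writes one SDF containing all hit conformers (aligned onto the query with
#' [icp_align()] when `align = TRUE`), one PQR per hit (radii and charges
#' assigned with the database's build parameters), and `report.tsv` with the
#' scores and ranks. An empty hit list writes only an empty report, with a
#' warning.
#'
#' @param hits A `lira_hits` from [query_db()].
#' @param library_sdf The library SDF the hits came from.
#' @param query The query molecule (needed for alignment).
#' @param out_dir Output directory (created if missing).
#' @param align Align each hit onto the query before export.
#' @param compound_tag Passed to [read_sdf()] when re-reading the library.
#' @return Invisible character vector of the files written.
#' @export
export_hits <- function(hits, library_sdf, query, out_dir, align = FALSE,
                        compound_tag = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(out_dir, "report.tsv")
  utils::write.table(as.data.frame(hits), report_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(hits) == 0) {
    warning("export_hits: empty hit list; only the report was written",
            call. = FALSE)
    return(invisible(report_path))
  }
  p <- attr(hits, "params")
  mols <- read_sdf(library_sdf, compound_tag = compound_tag)
  by_id <- stats::setNames(mols, vapply(mols, mol_id, ""))
  missing <- setdiff(hits$conformer_id, names(by_id))
  if (length(missing) > 0) {
    stop("export_hits: conformer id(s) not in library: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prep <- function(m) {
    m <- assign_radii(m, p$radius_table)
    assign_charges(m, p$charge_method)
  }
  query_prep <- if (align) prep(query) else NULL
  out_mols <- list()
  files <- report_path
  for (i in seq_len(nrow(hits))) {
    m <- prep(by_id[[hits$conformer_id[i]]])
    if (align) {
      fit <- icp_align(query_prep, m, L = p$L, probe_radius = p$probe_radius,
                       oversample_factor = p$oversample_factor)
      m <- fit$molecule
    }
    out_mols[[i]] <- m
    pqr <- file.path(out_dir, paste0(sanitize_filename(mol_id(m)), ".pqr"))
    write_pqr(m, pqr)
    files <- c(files, pqr)
  }
  sdf_path <- file.path(out_dir, "hits.sdf")
  write_sdf(out_mols, sdf_path)
  invisible(c(files, sdf_path))
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
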