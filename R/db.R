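# Descriptor database: a single-file columnar text container. Header lines
# ("#key=value") carry the build parameters that must match at query time;
# each data row holds one conformer's identity, totals and comma-joined
# per-degree amplitudes printed with %.17g so rebuilds and appends are
# byte-identical for identical inputs.

DB_MAGIC <- "#liraseek_descriptor_db"
DB_FORMAT_VERSION <- 1L

db_header_lines <- function(params) {
  c(DB_MAGIC,
    sprintf("#format_version=%d", DB_FORMAT_VERSION),
    sprintf("#L=%d", params$L),
    sprintf("#probe_radius=%.17g", params$probe_radius),
    sprintf("#charge_method=%s", params$charge_method),
    sprintf("#oversample_factor=%.17g", params$oversample_factor),
    sprintf("#radius_table=%s", params$radius_table),
    sprintf("#dielectric_model=%s", params$dielectric_model),
    paste(c("compound_id", "conformer_id", "shape_total", "esp_total",
            "shape_amplitudes", "esp_amplitudes"), collapse = "\t"))
}

descriptor_row <- function(d) {
  paste(c(
    d$compound_id, d$conformer_id,
    sprintf("%.17g", rif_total(d$shape_rif)),
    sprintf("%.17g", rif_total(d$esp_rif)),
    paste(sprintf("%.17g", d$shape_rif$amplitude), collapse = ","),
    paste(sprintf("%.17g", d$esp_rif$amplitude), collapse = ",")
  ), collapse = "\t")
}

#' Open a descriptor database
#'
#' @param path Path to a database written by [build_db()] or
#'   [write_descriptor_db()].
#' @return A `lira_db`: list with `params` (build parameters), `records`
#'   (tibble with identity columns, totals and amplitude list-columns) and
#'   `path`.
#' @export
read_descriptor_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != DB_MAGIC) {
    stop("read_descriptor_db: '", path, "' is not a descriptor database",
         call. = FALSE)
  }
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr[-1]), "=", fixed = TRUE)
  params <- stats::setNames(
    lapply(kv, function(p) p[2]),
    vapply(kv, function(p) p[1], "")
  )
  if (as.integer(params$format_version) != DB_FORMAT_VERSION) {
    stop("read_descriptor_db: unsupported format version ",
         params$format_version, call. = FALSE)
  }
  params <- list(
    L = as.integer(params$L),
    probe_radius = as.numeric(params$probe_radius),
    charge_method = params$charge_method,
    oversample_factor = as.numeric(params$oversample_factor),
    radius_table = params$radius_table %||% "bondi",
    dielectric_model = params$dielectric_model %||% "vacuum"
  )
  body <- lines[!grepl("^#", lines)]
  stopifnot(length(body) >= 1)
  body <- body[-1]  # column header
  recs <- if (length(body) == 0) {
    tibble::tibble(compound_id = character(), conformer_id = character(),
                   shape_total = numeric(), esp_total = numeric(),
                   shape_amplitudes = list(), esp_amplitudes = list())
  } else {
    tok <- strsplit(body, "\t", fixed = TRUE)
    tibble::tibble(
      compound_id = vapply(tok, `[`, "", 1),
      conformer_id = vapply(tok, `[`, "", 2),
      shape_total = as.numeric(vapply(tok, `[`, "", 3)),
      esp_total = as.numeric(vapply(tok, `[`, "", 4)),
      shape_amplitudes = lapply(tok, function(t)
        as.numeric(strsplit(t[5], ",", fixed = TRUE)[[1]])),
      esp_amplitudes = lapply(tok, function(t)
        as.numeric(strsplit(t[6], ",", fixed = TRUE)[[1]]))
    )
  }
  structure(list(params = params, records = recs, path = path),
            class = "lira_db")
}

#' Write descriptors to a database file
#'
#' @param descriptors List of `lira_descriptor` objects sharing one set of
#'   build parameters.
#' @param path Output path.
#' @param params Named list of build parameters (`L`, `probe_radius`,
#'   `charge_method`, `oversample_factor`, `radius_table`,
#'   `dielectric_model`).
#' @param append Append records to an existing database (parameters are
#'   checked against its header).
#' @return A `lira_db` handle for `path`, invisibly.
#' @export
write_descriptor_db <- function(descriptors, path, params, append = FALSE) {
  if (append && file.exists(path)) {
    existing <- read_descriptor_db(path)
    if (!identical(existing$params, params[names(existing$params)])) {
      stop("write_descriptor_db: build parameters do not match the existing ",
           "database", call. = FALSE)
    }
    cat(paste0(vapply(descriptors, descriptor_row, ""), "\n", collapse = ""),
        file = path, append = TRUE, sep = "")
  } else {
    writeLines(c(db_header_lines(params),
                 vapply(descriptors, descriptor_row, "")), path)
  }
  invisible(read_descriptor_db(path))
}

#' @export
print.lira_db <- function(x, ...) {
  cat(sprintf("# Descriptor database '%s': %d records, L = %d, probe %.2f A, charges '%s'\n",
              x$path %||% "?", nrow(x$records), x$params$L,
              x$params$probe_radius, x$params$charge_method))
  invisible(x)
}

#' One-line database summary
#'
#' @param x A `lira_db`.
#' @param ... Unused.
#' @return One-row tibble with the record count and build parameters.
#' @importFrom generics glance
#' @export
glance.lira_db <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_compounds = length(unique(x$records$compound_id)),
    L = x$params$L,
    probe_radius = x$params$probe_radius,
    charge_method = x$params$charge_method,
    oversample_factor = x$params$oversample_factor
  )
}

db_record_descriptor <- function(db, i) {
  r <- db$records[i, ]
  L <- db$params$L
  mk <- function(amp, channel) {
    structure(
      tibble::new_tibble(tibble::tibble(l = 0:L, amplitude = amp[[1]]),
                         class = "lira_rif"),
      total = sqrt(sum(amp[[1]]^2)), channel = channel, L = L
    )
  }
  structure(list(
    conformer_id = r$conformer_id, compound_id = r$compound_id,
    shape_rif = mk(r$shape_amplitudes, "shape"),
    esp_rif = mk(r$esp_amplitudes, "esp"), L = L
  ), class = "lira_descriptor")
}
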