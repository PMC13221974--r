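make_test_db <- function(n_compounds = 20, conformers_each = 2, seed = 71,
                         L = 6, planted_query = NULL, dir = tempdir()) {
  lib <- file.path(dir, sprintf("lib_s%d.sdf", seed))
  make_decoy_library(n_compounds, conformers_each, seed = seed, out_sdf = lib,
                     planted_query = planted_query)
  db_path <- file.path(dir, sprintf("lib_s%d.shdb", seed))
  db <- build_db(lib, db_path, L = L, charge_method = "zero")
  list(lib = lib, db = db, path = db_path)
}

test_that("database build counts records and is byte-deterministic", {
  withr::local_tempdir() -> td
  lib <- file.path(td, "lib.sdf")
  make_decoy_library(10, 2, seed = 72, out_sdf = lib)
  p1 <- file.path(td, "a.shdb"); p2 <- file.path(td, "b.shdb")
  db1 <- build_db(lib, p1, L = 6, charge_method = "zero")
  db2 <- build_db(lib, p2, L = 6, charge_method = "zero")
  expect_equal(nrow(db1$records), 20)
  expect_identical(readLines(p1), readLines(p2))
  g <- glance(db1)
  expect_equal(g$n_compounds, 10)
  expect_equal(g$L, 6)
})

test_that("records that fail descriptor generation are skipped with a warning", {
  withr::local_tempdir() -> td
  good <- make_synthetic_molecule(8, seed = 73, id = "good_conf1")
  bad <- molecule(data.frame(element = "Zq", x = 0, y = 0, z = 1),
                  id = "bad_conf1")
  lib <- file.path(td, "mixed.sdf")
  write_sdf(list(good, bad), lib)
  expect_warning(
    db <- build_db(lib, file.path(td, "m.shdb"), L = 6, charge_method = "zero"),
    "skipping conformer 'bad_conf1'"
  )
  expect_equal(nrow(db$records), 1)

  only_bad <- file.path(td, "bad.sdf")
  write_sdf(list(bad), only_bad)
  expect_error(
    suppressWarnings(build_db(only_bad, file.path(td, "b.shdb"), L = 6,
                              charge_method = "zero")),
    "no conformer"
  )
})

test_that("database read/write/append round trips bit-exactly", {
  withr::local_tempdir() -> td
  m <- make_synthetic_molecule(8, seed = 74)
  d <- describe_molecule(m, L = 6, charge_method = "zero")
  params <- list(L = 6L, probe_radius = 1.4, charge_method = "zero",
                 oversample_factor = 2, radius_table = "bondi",
                 dielectric_model = "vacuum")
  p <- file.path(td, "one.shdb")
  write_descriptor_db(list(d), p, params)
  db <- read_descriptor_db(p)
  expect_equal(db$records$shape_amplitudes[[1]], d$shape_rif$amplitude)
  expect_identical(db$params$L, 6L)

  # append preserves earlier bytes and checks parameters
  before <- readLines(p)
  d2 <- describe_molecule(make_synthetic_molecule(9, seed = 75), L = 6,
                          charge_method = "zero")
  write_descriptor_db(list(d2), p, params, append = TRUE)
  after <- readLines(p)
  expect_identical(after[seq_along(before)], before)
  expect_equal(nrow(read_descriptor_db(p)$records), 2)
  bad_params <- params; bad_params$probe_radius <- 0.9
  expect_error(write_descriptor_db(list(d2), p, bad_params, append = TRUE),
               "parameters")
  expect_error(suppressWarnings(read_descriptor_db(file.path(td, "lib_missing"))))
})

test_that("an exact library copy ranks first with score zero", {
  setup <- make_test_db(n_compounds = 15, seed = 76)
  mols <- read_sdf(setup$lib)
  q <- mols[[7]]
  hits <- query_db(setup$db, q, n = 5)
  expect_equal(hits$conformer_id[1], attr(q, "id"))
  expect_lt(hits$score[1], 1e-12)
})

test_that("a jittered planted copy is retrieved at rank one among decoys", {
  q <- make_synthetic_molecule(12, seed = 77, id = "query")
  setup <- make_test_db(n_compounds = 30, seed = 78, planted_query = q)
  hits <- query_db(setup$db, q, n = 10)
  expect_equal(hits$compound_id[1], "PLANTED")
  expect_lt(hits$score[1], hits$score[2])
})

test_that("rank order is invariant under rigid motion of the query", {
  q <- make_synthetic_molecule(12, seed = 79, id = "query")
  setup <- make_test_db(n_compounds = 12, seed = 80)
  h1 <- query_db(setup$db, q, n = 24)
  moved <- apply_transform(q, euler_to_matrix(1.9, 0.8, 0.3), c(8, -3, 1))
  h2 <- query_db(setup$db, moved, n = 24)
  # scores move by at most ~1e-3 relative, and hits whose scores are well
  # separated from their neighbours keep their positions
  m <- match(h1$conformer_id, h2$conformer_id)
  expect_equal(h2$score[m], h1$score, tolerance = 1e-3)
  gap <- pmin(c(Inf, diff(h1$score)), c(diff(h1$score), Inf))
  separated <- gap > 2e-3 * max(h1$score)
  expect_identical(h2$conformer_id[separated], h1$conformer_id[separated])
})

test_that("scores are bit-identical across repeated scans", {
  q <- make_synthetic_molecule(12, seed = 81, id = "query")
  setup <- make_test_db(n_compounds = 8, seed = 82)
  h1 <- query_db(setup$db, q, n = 16)
  h2 <- query_db(read_descriptor_db(setup$path), q, n = 16)
  expect_identical(h1$score, h2$score)
})

test_that("the per-compound conformer cap is enforced", {
  q <- make_synthetic_molecule(10, seed = 83, id = "query")
  setup <- make_test_db(n_compounds = 4, conformers_each = 8, seed = 84)
  hits_all <- query_db(setup$db, q, n = 32, per_compound_cap = 8)
  expect_equal(nrow(hits_all), 32)
  hits1 <- query_db(setup$db, q, n = 32, per_compound_cap = 1)
  expect_false(any(duplicated(hits1$compound_id)))
  hits5 <- query_db(setup$db, q, n = 32, per_compound_cap = 5)
  expect_true(all(table(hits5$compound_id) <= 5))
})

test_that("band-limit mismatch between query descriptor and db is caught", {
  setup <- make_test_db(n_compounds = 3, seed = 85)
  q <- make_synthetic_molecule(10, seed = 86)
  qd <- describe_molecule(q, L = 15, charge_method = "zero")
  expect_error(query_db(setup$db, qd), "does not match database")
})

test_that("hit export writes SDF, per-hit PQR and a score report", {
  withr::local_tempdir() -> td
  q <- make_synthetic_molecule(12, seed = 87, id = "query")
  setup <- make_test_db(n_compounds = 6, seed = 88, dir = td)
  hits <- query_db(setup$db, q, n = 4)
  out <- file.path(td, "results")
  export_hits(hits, setup$lib, q, out, align = FALSE)
  expect_true(file.exists(file.path(out, "hits.sdf")))
  expect_length(read_sdf(file.path(out, "hits.sdf")), 4)
  expect_length(list.files(out, pattern = "\\.pqr$"), 4)
  rep <- utils::read.delim(file.path(out, "report.tsv"))
  expect_equal(nrow(rep), 4)
  expect_true(all(c("rank", "conformer_id", "score") %in% names(rep)))

  # unknown conformer id errors by name
  bad <- hits
  bad$conformer_id[1] <- "GHOST_conf9"
  expect_error(export_hits(bad, setup$lib, q, out), "GHOST_conf9")

  # empty hit list: report only, with warning
  empty <- hits[0, ]
  attr(empty, "params") <- attr(hits, "params")
  out2 <- file.path(td, "empty")
  expect_warning(export_hits(empty, setup$lib, q, out2), "empty hit list")
  expect_false(file.exists(file.path(out2, "hits.sdf")))
})

test_that("aligned export reproduces a rotated query's coordinates", {
  withr::local_tempdir() -> td
  q <- make_synthetic_molecule(12, seed = 89, id = "query")
  rotated <- apply_transform(q, euler_to_matrix(0.7, 1.2, 2.5), c(4, 1, -2))
  rotated <- liraseek:::set_mol_attr(rotated, "id", "ROT_conf1")
  rotated <- liraseek:::set_mol_attr(rotated, "compound_id", "ROT")
  lib <- file.path(td, "lib.sdf")
  write_sdf(list(rotated), lib)
  db <- build_db(lib, file.path(td, "lib.shdb"), L = 10, charge_method = "zero")
  hits <- query_db(db, q, n = 1)
  out <- file.path(td, "aligned")
  export_hits(hits, lib, q, out, align = TRUE)
  back <- read_sdf(file.path(out, "hits.sdf"))[[1]]
  expect_lt(atom_rmsd(back, q), 0.1)
})
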