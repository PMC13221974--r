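test_that("SDF write -> read round trip preserves structure and tags", {
  mols <- list(
    make_synthetic_molecule(8, seed = 1, id = "a_conf1"),
    make_synthetic_molecule(5, seed = 2, id = "b_conf1"),
    make_synthetic_molecule(12, seed = 3, id = "c_conf2")
  )
  mols[[1]] <- liraseek:::set_mol_attr(mols[[1]], "properties",
                                       c(ic50 = "4.2", series = "A"))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(nrow(back[[i]]), nrow(mols[[i]]))
    expect_equal(back[[i]]$element, mols[[i]]$element)
    # coordinates round-trip bit-identically at the printed precision
    expect_identical(back[[i]]$x, round(mols[[i]]$x, 4))
    expect_identical(back[[i]]$z, round(mols[[i]]$z, 4))
  }
  expect_equal(attr(back[[1]], "properties")[["ic50"]], "4.2")
  expect_equal(attr(back[[1]], "id"), "a_conf1")
  expect_equal(attr(back[[1]], "compound_id"), "a")

  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(back, path2)
  back2 <- read_sdf(path2)
  path3 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(back2, path3)
  expect_identical(readLines(path2), readLines(path3))
})

test_that("SDF reader handles degenerate inputs per policy", {
  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(), empty)
  expect_error(read_sdf(empty), "no records")

  # 2D structure (all z zero) is a warning, not an error
  flat <- single_atom(c(1, 2, 0))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(flat), path)
  expect_warning(read_sdf(path), "2D structure suspected")

  # empty molecule list writes an empty file without error
  out <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(), out)
  expect_identical(readLines(out), character(0))
})

test_that("methane fixture reads back with five atoms and carbon-centred cog", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(methane()), path)
  m <- read_sdf(path)[[1]]
  expect_equal(nrow(m), 5)
  expect_equal(sum(grepl("^H$", m$element)), 4)
  expect_equal(center_of_geometry(m), c(0, 0, 0), tolerance = 1e-6)
})

test_that("V3000 records are readable", {
  lines <- c(
    "v3k_mol", "  test", "",
    "  0  0  0  0  0  0  0  0  0  0999 V3000",
    "M  V30 BEGIN CTAB",
    "M  V30 COUNTS 2 1 0 0 0",
    "M  V30 BEGIN ATOM",
    "M  V30 1 C 0.0 0.0 0.0 0",
    "M  V30 2 O 1.2 0.0 0.5 0",
    "M  V30 END ATOM",
    "M  V30 BEGIN BOND",
    "M  V30 1 2 1 2",
    "M  V30 END BOND",
    "M  V30 END CTAB",
    "M  END", "$$$$"
  )
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(lines, path)
  m <- read_sdf(path)[[1]]
  expect_equal(m$element, c("C", "O"))
  expect_equal(m$x, c(0, 1.2))
  expect_equal(attr(m, "bonds")$order, 2L)
})

test_that("PQR round trip preserves charges and radii exactly", {
  m <- make_synthetic_molecule(8, seed = 4)
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(m, path)
  lines <- readLines(path)
  expect_length(lines, 8)
  expect_true(all(grepl("^ATOM", lines)))
  back <- read_pqr(path)
  expect_equal(back$charge, round(m$charge, 4))
  expect_equal(back$radius, round(m$radius, 4))
  expect_equal(back$element, m$element)
})

test_that("PQR reader parses literal lines and rejects truncated ones", {
  path <- withr::local_tempfile(fileext = ".pqr")
  writeLines("ATOM 1 C RES 1 0.0 0.0 0.0 -0.1 1.7", path)
  m <- read_pqr(path)
  expect_equal(nrow(m), 1)
  expect_equal(m$charge, -0.1)
  expect_equal(m$radius, 1.7)

  writeLines("ATOM 1 C RES 1 0.0 0.0", path)
  expect_error(read_pqr(path), "line 1")

  writeLines("REMARK nothing here", path)
  expect_error(read_pqr(path), "no atoms")

  # unset charges refuse to write
  m2 <- single_atom(radius = 1.7)
  expect_error(write_pqr(m2, path), "unset charges")
})

test_that("PDB reader counts HETATM records and round trips at 3 decimals", {
  m <- make_synthetic_molecule(10, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  back <- read_pdb(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$x, round(m$x, 3))
  expect_true(all(is.na(back$radius)))
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, path2)
  expect_identical(readLines(path), readLines(path2))

  writeLines("REMARK empty", path)
  expect_error(read_pdb(path), "no atoms")
})

test_that("PDB altloc duplicates keep the first altloc with a warning", {
  lines <- c(
    "HETATM    1  C1 ALIG A   1       0.000   0.000   0.000  0.50  0.00           C",
    "HETATM    1  C1 BLIG A   1       1.000   0.000   0.000  0.50  0.00           C",
    "HETATM    2  O1  LIG A   1       2.000   0.000   0.000  1.00  0.00           O",
    "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_warning(m <- read_pdb(path), "alternate-location")
  expect_equal(nrow(m), 2)
  expect_equal(m$x, c(0, 2))
})

test_that("Bondi radius assignment matches the shipped table and is idempotent", {
  m <- methane()
  m <- assign_radii(m)
  expect_equal(m$radius, c(1.70, 1.20, 1.20, 1.20, 1.20))
  expect_identical(assign_radii(m)$radius, m$radius)
  bad <- single_atom(element = "Xx")
  expect_error(assign_radii(bad), "Xx")
})

test_that("charge models behave per contract", {
  m <- assign_radii(methane())
  z <- assign_charges(m, "zero")
  expect_true(all(z$charge == 0))
  expect_equal(attr(z, "properties")[["total_charge"]], "0")

  # 'file' keeps existing charges and refuses when absent
  pq <- make_synthetic_molecule(6, seed = 6)
  expect_identical(assign_charges(pq, "file")$charge, pq$charge)
  expect_error(assign_charges(m, "file"), "no charges")

  # gasteiger needs connectivity
  pdb_like <- single_atom(c(0, 0, 0))
  expect_error(assign_charges(pdb_like, "gasteiger"), "PQR")
})

test_that("Gasteiger charges on methane are symmetric and neutral", {
  skip_if(Sys.which("obabel") == "", "obabel not on PATH")
  m <- assign_charges(assign_radii(methane()), "gasteiger")
  h <- m$charge[m$element == "H"]
  expect_equal(max(h) - min(h), 0, tolerance = 1e-6)
  expect_equal(sum(m$charge), 0, tolerance = 1e-6)
  expect_lt(m$charge[1], 0)  # carbon carries the compensating negative charge
})
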