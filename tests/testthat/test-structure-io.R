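test_that("single- and multi-model PDB files read with counts preserved", {
  f1 <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"),
                      n_models = 1L, n_res = 5L)
  e1 <- read_pdb_models(f1)
  expect_equal(n_models(e1), 1L)
  expect_equal(n_atoms(e1), 20L)

  f3 <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"),
                      n_models = 3L, n_res = 4L)
  e3 <- read_pdb_models(f3)
  expect_equal(n_models(e3), 3L)
  expect_equal(e3$model_ids, c("1", "2", "3"))
  expect_identical(atom_keys(e3), atom_keys(e3))
})

test_that("het_policy strip removes ligands and waters, and is idempotent", {
  f <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"),
                     n_models = 2L, n_res = 3L, with_het = TRUE)
  stripped <- read_pdb_models(f, het_policy = "strip")
  expect_false(any(stripped$atoms$resid %in% c("HEM", "HOH")))
  expect_equal(n_atoms(stripped), 12L)
  kept <- read_pdb_models(f, het_policy = "keep")
  expect_equal(n_atoms(kept), 14L)
  # idempotence: stripping an already-stripped file changes nothing
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(stripped, f2)
  again <- read_pdb_models(f2, het_policy = "strip")
  expect_identical(atom_keys(again), atom_keys(stripped))
  expect_equal(again$xyz, stripped$xyz, tolerance = 1e-12)
})

test_that("write/read round trip preserves coordinates to PDB precision", {
  spec <- synthetic_spec(n_models = 4L, seed = 11L)
  ens <- sample_two_state_ensemble(spec)$ensemble
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(ens, f)
  back <- read_pdb_models(f)
  expect_identical(atom_keys(back), atom_keys(ens))
  expect_equal(back$xyz, ens$xyz, tolerance = 5e-4)
  expect_true(max(abs(back$xyz - ens$xyz)) <= 5e-4 + 1e-12)
})

test_that("altlocs resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA AALA A   1       2.000   0.000   0.000  0.40  0.00",
    "ATOM      3  CA BALA A   1       3.000   0.000   0.000  0.60  0.00",
    "ATOM      4  C   ALA A   1       4.000   0.000   0.000  1.00  0.00",
    "ATOM      5  O   ALA A   1       5.000   0.000   0.000  1.00  0.00",
    "END"), f)
  e <- read_pdb_models(f)
  expect_equal(n_atoms(e), 4L)
  ca <- model_coords(e, 1L)[e$atoms$elety == "CA", ]
  expect_equal(unname(ca[1]), 3.0)  # occupancy 0.60 altloc B wins
})

test_that("insertion codes are rejected with a clear error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  ALA A   1A      3.000   0.000   0.000  1.00  0.00",
    "END"), f)
  expect_error(read_pdb_models(f), "insertion codes")
})

test_that("directory mode rejects topology-inconsistent models by id", {
  d <- withr::local_tempdir()
  write_toy_pdb(file.path(d, "a.pdb"), n_res = 4L)
  write_toy_pdb(file.path(d, "b.pdb"), n_res = 4L)
  write_toy_pdb(file.path(d, "c.pdb"), n_res = 5L)  # different atom set
  expect_warning(e <- read_pdb_models(d), "c")
  expect_equal(n_models(e), 2L)
  expect_setequal(e$model_ids, c("a", "b"))
})

test_that("energy tables validate header, finiteness and uniqueness", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model_id,energy_kcal_mol", "m1,-700.0", "m2,-650.5"), f)
  et <- read_energy_table(f)
  expect_s3_class(et, "energy_table")
  expect_equal(nrow(et), 2L)
  expect_equal(unname(lookup_energies(et, "m2")), -650.5)

  writeLines("model_id,energy_kcal_mol", f)
  expect_error(read_energy_table(f), "no entries")

  writeLines(c("model_id,energy_kcal_mol", "m1,-700.0", "m2,NaN"), f)
  expect_error(read_energy_table(f), "m2")

  writeLines(c("model_id,energy_kcal_mol", "m1,-700.0", "m1,-650.5"), f)
  expect_error(read_energy_table(f), "duplicate")

  writeLines(c("id,energy", "m1,-700.0"), f)
  expect_error(read_energy_table(f), "header")
})

test_that("atom selection honours selection type and regions", {
  f <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"), n_res = 10L)
  e <- read_pdb_models(f)
  expect_equal(n_atoms(extract_atoms(e, "backbone")), 40L)
  expect_equal(n_atoms(extract_atoms(e, "backbone", include_o = FALSE)), 30L)
  reg <- region_spec("mid", "A", 3L, 5L)
  expect_equal(n_atoms(extract_atoms(e, "calpha", regions = reg)), 3L)
  expect_error(extract_atoms(e, "calpha", regions = region_spec("x", "A", 99L, 120L)),
               "empty selection")
  expect_error(extract_atoms(e, "calpha", regions = region_spec("x", "B", 1L, 5L)),
               "chain")
  # composing backbone then calpha equals calpha directly
  bb_then_ca <- extract_atoms(extract_atoms(e, "backbone"), "calpha")
  expect_identical(atom_keys(bb_then_ca), atom_keys(extract_atoms(e, "calpha")))
  expect_equal(bb_then_ca$xyz, extract_atoms(e, "calpha")$xyz)
})

test_that("region config files parse and validate", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# adenylate kinase subdomains",
               "ATP_lid A 26 78",
               "AMP_lid A 121 160",
               "CORE A 79 214"), f)
  rg <- read_region_config(f)
  expect_equal(rg$name, c("ATP_lid", "AMP_lid", "CORE"))
  expect_equal(rg$first, c(26L, 121L, 79L))
  expect_error(region_spec("bad", "A", 10, 5), "first <= last")
})
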