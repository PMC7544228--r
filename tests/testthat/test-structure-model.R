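test_that("a written single-guanosine fixture reads back as one model, one residue", {
  res <- build_nucleotide("G", chi = 240, P = 162, tau_m = 38)
  ens <- g4conform:::new_g4_ensemble(res)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  back <- read_structure(path)
  expect_length(ensemble_models(back), 1)
  expect_length(model_residues(ensemble_model(back, 1)), 1)
})

test_that("read/write/read round trips preserve coordinates and classifications", {
  mk <- fixture_mock("vloop_conventional", sigma = 0.2, n_models = 3, seed = 7)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(mk$ensemble, p1)
  e1 <- read_structure(p1)
  write_pdb(e1, p2)
  e2 <- read_structure(p2)
  expect_equal(as.matrix(e1$atoms[, c("x", "y", "z")]),
               as.matrix(e2$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
  r1 <- model_residues(ensemble_model(e1, 1), nucleotides = TRUE)
  r2 <- model_residues(ensemble_model(e2, 1), nucleotides = TRUE)
  expect_identical(vapply(r1, classify_sugar_chemistry, character(1)),
                   vapply(r2, classify_sugar_chemistry, character(1)))
  expect_identical(vapply(r1, base_type, character(1)),
                   vapply(r2, base_type, character(1)))
})

test_that("coordinates agree with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  mk <- fixture_mock("parallel", sigma = 0, n_models = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(mk$ensemble, path)
  mine <- read_structure(path)
  theirs <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  expect_equal(mine$atoms$x, theirs$atom$x, tolerance = 1e-6)
  expect_equal(mine$atoms$y, theirs$atom$y, tolerance = 1e-6)
  expect_equal(trimws(g4conform:::normalize_atom_name(theirs$atom$elety)),
               trimws(mine$atoms$elety))
})

test_that("models with mismatched atom inventories raise an error naming the residue", {
  res <- build_nucleotide("G", chi = 240, P = 162, tau_m = 38)
  ens <- g4conform:::new_g4_ensemble(res)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  two <- c("MODEL        1", atom_lines, "ENDMDL",
           "MODEL        2", atom_lines[-3], "ENDMDL", "END")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two, p2)
  expect_error(read_structure(p2), "inventory error.*A 1")
})

test_that("atom-name dialects are unified and altlocs other than A dropped", {
  rec <- function(serial, name, altloc, x) {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, altloc, "DG", "A", 1L, x, 2, 3)
  }
  lines <- c(rec(1, " O4*", " ", 1),
             rec(2, " O1P", " ", 1.5),
             rec(3, " C1'", "A", 2),
             rec(4, " C1'", "B", 9),
             "END")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, p)
  ens <- read_structure(p)
  expect_true("O4'" %in% ens$atoms$elety)
  expect_true("OP1" %in% ens$atoms$elety)
  expect_equal(sum(ens$atoms$elety == "C1'"), 1)
  expect_equal(ens$atoms$x[ens$atoms$elety == "C1'"], 2)
})

test_that("mmCIF atom_site loops read identically to the PDB form", {
  res <- build_nucleotide("G", chi = 60, P = 18, tau_m = 38, chemistry = "locked")
  cif <- c(
    "data_fixture", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.auth_atom_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.label_alt_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.pdbx_PDB_model_num",
    sprintf('ATOM %d %s "%s" LNG A 1 . %.3f %.3f %.3f 1',
            seq_len(nrow(res)), res$elem, res$elety, res$x, res$y, res$z),
    "#")
  p <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, p)
  ens <- read_structure(p)
  expect_equal(ens$provenance$format, "mmcif")
  r <- model_residues(ensemble_model(ens, 1), nucleotides = TRUE)[[1]]
  expect_equal(sort(r$elety), sort(res$elety))
  expect_equal(classify_sugar_chemistry(r), "locked")
  ## 0.001 A coordinate precision moves chi by a few hundredths of a degree
  expect_equal(glycosidic_chi(r), 60, tolerance = 0.1)
})

test_that("sugar chemistry is derived from atoms, never the residue code", {
  cases <- c(deoxyribose = "deoxyribose", ribose = "ribose",
             locked = "locked", `2'F-ribo` = "2'F-ribo",
             `2'F-arabino` = "2'F-arabino")
  for (chem in names(cases)) {
    res <- build_nucleotide("G", chi = 240, P = 18, tau_m = 40, chemistry = chem)
    res$resid <- "XXX"  # misleading residue code must not matter
    expect_identical(classify_sugar_chemistry(res), unname(cases[[chem]]))
    moved <- rigid_move(res, seed = 11)
    expect_identical(classify_sugar_chemistry(moved), unname(cases[[chem]]))
  }
  ## missing ring atoms degrade to unknown without an exception
  res <- build_nucleotide("G")
  expect_identical(classify_sugar_chemistry(res[res$elety != "O4'", ]),
                   "unknown")
})
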