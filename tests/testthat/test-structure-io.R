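test_that("a synthetic duplex round-trips through write/read", {
  d <- buildIdealBDNA("ACGTACGTACGT")
  f <- tempfile(fileext = ".pdb")
  makeMockCrystal(atoms(d), UnitCell(100, 100, 100), path = f)
  m <- readStructure(f)
  expect_s4_class(m, "CrystalModel")
  expect_identical(sort(nucleicChains(m)), c("A", "B"))
  expect_identical(nrow(ions(m)), 0L)
  ## append one Mg HETATM
  lines <- readLines(f)
  mg <- sprintf("HETATM%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                9999L, "MG  ", "", "MG", "M", 1L, "", 5, 5, 5, 1, 0, "MG")
  writeLines(c(lines[lines != "END"], mg, "END"), f)
  m2 <- readStructure(f)
  expect_identical(nrow(ions(m2)), 1L)
  expect_identical(ions(m2)$element, "Mg")
  expect_true(ions(m2)$divalent)
  ## write -> read preserves atoms and positions (to PDB precision)
  f2 <- tempfile(fileext = ".pdb")
  writeStructure(m2, f2)
  m3 <- readStructure(f2)
  expect_identical(nrow(atoms(m3)), nrow(atoms(m2)))
  expect_identical(atoms(m3)$name, atoms(m2)$name)
  expect_lt(max(abs(xyzOf(atoms(m3)) - xyzOf(atoms(m2)))), 1e-3 + 1e-12)
  expect_identical(nrow(ions(m3)), 1L)
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  hdr <- "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1"
  mk <- function(serial, alt, occ, x) {
    sprintf("ATOM  %5d  C1'%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, alt, "DC", "A", 1L, x, 0, 0, occ, 0)
  }
  f <- tempfile(fileext = ".pdb")
  writeLines(c(hdr, mk(1, "A", 0.4, 1), mk(2, "B", 0.6, 2),
               mk(3, "A", 0.5, 3), "END"), f)
  m <- readStructure(f)
  ## one atom kept; highest occupancy (0.6, x = 2)
  expect_identical(nrow(atoms(m)), 1L)
  expect_equal(atoms(m)$x, 2)
  ## tie: first in file wins
  writeLines(c(hdr, mk(1, "A", 0.5, 1), mk(2, "B", 0.5, 2), "END"), f)
  m2 <- readStructure(f)
  expect_equal(atoms(m2)$x, 1)
})

test_that("symmetry-operator parsing round-trips over the whole table", {
  for (sg in knownSpaceGroups()) {
    ops <- spaceGroupOperators(sg)
    for (op in ops) {
      expect_true(abs(abs(det(op@rot)) - 1) < 1e-12)
      op2 <- parseSymop(symopLabel(op))
      expect_equal(op2@rot, op@rot, tolerance = 1e-12)
      expect_equal(op2@trans %% 1, op@trans %% 1, tolerance = 1e-12)
    }
  }
  expect_error(spaceGroupOperators("X 9 9 9"), "operators unavailable")
})

test_that("ion extraction skips waters, drugs and protein C-alpha atoms", {
  row <- function(rec, serial, name, resn, chain, el) {
    data.frame(record = rec, serial = serial, name = name, altloc = "",
               resn = resn, chain = chain, resi = serial, icode = "",
               x = serial, y = 0, z = 0, occ = 1, element = el,
               stringsAsFactors = FALSE)
  }
  at <- rbind(
    row("HETATM", 1, "O", "HOH", "W", "O"),      # water
    row("HETATM", 2, "C1", "NT", "X", "C"),      # drug carbon (netropsin)
    row("HETATM", 3, "N1", "NT", "X", "N"),
    row("ATOM",   4, "CA", "ALA", "P", "C"),     # protein C-alpha
    row("HETATM", 5, "MG", "MG", "M", "Mg"),
    row("HETATM", 6, "NA", "NA", "M", "Na"),
    row("HETATM", 7, "CO", "NCO", "M", "Co"))    # cobalt hexammine metal
  m <- makeCrystalModel(at, cell = UnitCell(50, 50, 50))
  expect_identical(sort(ions(m)$element), c("Co", "Mg", "Na"))
  expect_identical(ions(m)$divalent[order(ions(m)$element)],
                   c(TRUE, TRUE, FALSE))
})

test_that("a model without a cell is written as dummy P1 with a warning", {
  d <- buildIdealBDNA("ACGTACGT")
  m <- makeCrystalModel(atoms(d), cell = NULL)
  f <- tempfile(fileext = ".pdb")
  expect_warning(writeStructure(m, f), "dummy")
  m2 <- readStructure(f)
  expect_equal(unitCell(m2)@a, 1)
  expect_identical(nrow(atoms(m2)), nrow(atoms(m)))
})

test_that("minimal mmCIF files parse: cell, operators, atoms", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_mock",
    "_cell.length_a    25.000",
    "_cell.length_b    30.000",
    "_cell.length_c    40.000",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 21 21 21'",
    "loop_",
    "_symmetry_equiv.pos_as_xyz",
    "'x,y,z'",
    "'x+1/2,-y+1/2,-z'",
    "'-x,y+1/2,-z+1/2'",
    "'-x+1/2,-y,z+1/2'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "ATOM 1 C \"C1'\" DG A 1 1.000 2.000 3.000 1.00",
    "ATOM 2 N N9 DG A 1 2.500 2.000 3.000 1.00",
    "HETATM 3 MG MG MG M 1 9.000 9.000 9.000 1.00"), f)
  m <- readStructure(f)
  expect_equal(unitCell(m)@b, 30)
  expect_identical(unitCell(m)@spaceGroup, "P 21 21 21")
  expect_length(symOperators(m), 4)
  expect_identical(nrow(atoms(m)), 3L)
  expect_identical(atoms(m)$name[1], "C1'")
  expect_identical(nrow(ions(m)), 1L)
})

test_that("unreadable input fails with a format error", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HELLO", "WORLD"), f)
  expect_error(readStructure(f), "format error")
  expect_error(readStructure(tempfile()), "not found")
})
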