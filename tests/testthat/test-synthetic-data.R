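test_that("the ideal builder obeys its stated geometry", {
  d <- buildIdealBDNA("CCGCCGGCGG")   # 10-mer
  o <- pairOrigins(d)
  expect_equal(sqrt(sum((o[10, ] - o[1, ])^2)), 9 * 3.38, tolerance = 1e-9)
  ## self-complementary decamer: both strands read the same 5'->3'
  sq <- duplexSequences(d)
  expect_identical(unname(sq["I"]), "CCGCCGGCGG")
  expect_identical(unname(sq["II"]), "CCGCCGGCGG")
  ## all pairs detected as Watson-Crick
  expect_identical(nrow(d@pairs), 10L)
  expect_true(all(d@pairs$type == "WC"))
  expect_error(buildIdealBDNA("ACGX"), "unknown base")
})

test_that("the builder is deterministic given (params, seed)", {
  d1 <- buildIdealBDNA("ACGTACGT", noiseSigma = 0.3, seed = 11)
  d2 <- buildIdealBDNA("ACGTACGT", noiseSigma = 0.3, seed = 11)
  d3 <- buildIdealBDNA("ACGTACGT", noiseSigma = 0.3, seed = 12)
  expect_identical(atoms(d1), atoms(d2))
  expect_false(isTRUE(all.equal(atoms(d1)$x, atoms(d3)$x)))
})

test_that("posed crossovers reproduce the requested pose exactly", {
  for (al in c(-75.5, -30, 12.25, 60, 90)) {
    for (dd in c(15, 21.7)) {
      cr <- buildCrossover(al, dd)
      dups <- list(cr$duplexA, cr$duplexB)
      cx <- findCrossovers(dups, maxDistance = 30)[[1]]
      expect_equal(alphaDeg(cx), al, tolerance = 1e-6)
      expect_equal(interaxialDistance(cx), dd, tolerance = 1e-6)
    }
  }
  expect_warning(buildCrossover(60, 9, mode = "groove_groove_major"),
                 "clash")
})

test_that("mirroring is an involution that flips chirality but not mode", {
  cr <- buildCrossover(60, 18, mode = "groove_backbone_major")
  m1 <- mirrorAssembly(cr$atoms)
  expect_equal(measureAlpha(m1), -60, tolerance = 1e-9)
  m2 <- mirrorAssembly(m1)
  expect_identical(m2, cr$atoms)
  ## distances are preserved by the improper isometry
  sub <- seq(1, nrow(cr$atoms), by = 13)
  expect_equal(as.numeric(dist(xyzOf(m1[sub, ]))),
               as.numeric(dist(xyzOf(cr$atoms[sub, ]))), tolerance = 1e-12)
  ## the mirrored construct still classifies as groove-backbone, with
  ## handedness flipped
  dups <- duplexesFromAtoms(m1)
  cx <- findCrossovers(dups)[[1]]
  expect_identical(handedness(cx), "left")
  expect_identical(contactMode(classifyMode(cx)), "MAJOR_GROOVE_BACKBONE")
})

test_that("mock crystals reconstruct the designed assembly", {
  ## isolated: only the identity copy within 20 A
  d <- buildIdealBDNA("ACGTACGTACGT")
  f <- tempfile(fileext = ".pdb")
  makeMockCrystal(d, UnitCell(100, 100, 100), path = f)
  expect_length(expandNeighborhood(readStructure(f), radius = 20), 1)
  ## a designed crossover survives the write/read/analyse round trip
  cr <- buildCrossover(-42.75, 19.5, mode = "groove_groove_major")
  f2 <- tempfile(fileext = ".pdb")
  makeMockCrystal(list(cr$duplexA, cr$duplexB), UnitCell(120, 120, 120),
                  path = f2)
  res <- analyzeStructure(f2)
  expect_identical(nrow(res$table), 1L)
  ## PDB coordinates carry 3 decimals, so the recovered angle is exact only
  ## to ~1e-3 degrees
  expect_equal(res$table$alpha_exact, -42.75, tolerance = 1e-4)
  expect_identical(res$table$mode, "Major <> Major")
  ## an oversized molecule cannot be packed into a tiny cell
  expect_error(makeMockCrystal(d, UnitCell(5, 5, 5), path = tempfile()),
               "larger than cell")
})
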