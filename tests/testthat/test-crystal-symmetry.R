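test_that("orthogonalization follows the standard convention", {
  expect_equal(orthogonalizationMatrix(UnitCell(10, 10, 10)), 10 * diag(3))
  M <- orthogonalizationMatrix(UnitCell(30, 30, 90, gamma = 120))
  expect_equal(sqrt(colSums(M^2)), c(30, 30, 90))          # axis lengths
  expect_equal(as.numeric(M %*% c(1, 0, 0)), c(30, 0, 0))  # a along x
  expect_equal(M[3, 2], 0)                                  # b in xy-plane
  ## angles violating the triangle inequality give a non-positive volume
  expect_error(UnitCell(10, 10, 10, alpha = 60, beta = 60, gamma = 150),
               "degenerate|volume")
})

test_that("det(orthogonalization) equals the closed-form triclinic volume", {
  ## independent oracle: V = abc sqrt(1 - ca^2 - cb^2 - cg^2 + 2 ca cb cg)
  for (s in 1:20) {
    set.seed(s)
    len <- runif(3, 10, 80)
    ang <- runif(3, 60, 120)
    cl <- UnitCell(len[1], len[2], len[3], ang[1], ang[2], ang[3])
    ca <- cos(ang[1] * pi / 180); cb <- cos(ang[2] * pi / 180)
    cg <- cos(ang[3] * pi / 180)
    vol <- prod(len) * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
    expect_equal(det(orthogonalizationMatrix(cl)), vol, tolerance = 1e-9)
  }
})

test_that("an isolated molecule in a big P1 cell yields only the identity", {
  d <- buildIdealBDNA("ACGTACGTACGT")
  f <- tempfile(fileext = ".pdb")
  makeMockCrystal(d, UnitCell(100, 100, 100), path = f)
  copies <- expandNeighborhood(readStructure(f), radius = 20)
  expect_length(copies, 1)
  expect_true(copies[[1]]@isIdentity)
})

test_that("P1 copy counts match brute-force lattice enumeration", {
  ## tight cell: many lattice contacts; oracle enumerates shifts in [-3,3]^3
  d <- buildIdealBDNA("ACGTACGT")
  for (cellDims in list(c(25, 25, 40), c(22, 30, 35))) {
    f <- tempfile(fileext = ".pdb")
    makeMockCrystal(d, UnitCell(cellDims[1], cellDims[2], cellDims[3]),
                    path = f)
    m <- readStructure(f)
    radius <- 18
    copies <- expandNeighborhood(m, radius = radius)
    expect_identical(length(copies), as.integer(bruteP1Copies(m, radius)))
  }
})

test_that("placed copies are rigid and proper for mirror-free space groups", {
  d <- buildIdealBDNA("ACGTACGT")
  f <- tempfile(fileext = ".pdb")
  makeMockCrystal(d, UnitCell(35, 35, 45, gamma = 120, spaceGroup = "P 31 2 1"),
                  path = f)
  m <- readStructure(f)
  copies <- expandNeighborhood(m, radius = 18)
  expect_gt(length(copies), 1)
  ref <- atoms(m)
  refd <- dist(xyzOf(ref[seq(1, nrow(ref), by = 7), ]))
  for (cp in copies) {
    ## proper isometry in the orthogonal frame
    expect_equal(det(cp@rot), 1, tolerance = 1e-9)
    ## rigidity: intra-copy distances match the source to 1e-6
    cpd <- dist(xyzOf(atoms(cp)[seq(1, nrow(ref), by = 7), ]))
    expect_lt(max(abs(cpd - refd)), 1e-6)
  }
  ## every operator of every tabulated (Sohncke) group is proper in the
  ## orthogonal frame of a generic cell
  M <- orthogonalizationMatrix(UnitCell(30, 40, 50, 80, 95, 110))
  for (sg in knownSpaceGroups()) {
    for (op in spaceGroupOperators(sg)) {
      expect_equal(det(M %*% op@rot %*% solve(M)), 1, tolerance = 1e-9)
    }
  }
})

test_that("expansion is monotone in radius and idempotent", {
  d <- buildIdealBDNA("ACGTACGT")
  f <- tempfile(fileext = ".pdb")
  makeMockCrystal(d, UnitCell(26, 26, 40), path = f)
  m <- readStructure(f)
  key <- function(cp) paste(round(c(cp@rot, cp@trans), 6), collapse = ",")
  small <- vapply(expandNeighborhood(m, radius = 10), key, character(1))
  big <- vapply(expandNeighborhood(m, radius = 22), key, character(1))
  expect_true(all(small %in% big))
  again <- vapply(expandNeighborhood(m, radius = 22), key, character(1))
  expect_identical(sort(big), sort(again))
})
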