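mkAxis <- function(point, dir, ext = c(-20, 20)) {
  new("HelicalAxisFit", point = point, direction = dir / sqrt(sum(dir^2)),
      rmsd = 0, curvatureFlag = FALSE, extents = ext)
}

test_that("closest approach handles perpendicular, identical and skew axes", {
  a <- mkAxis(c(0, 0, 0), c(0, 0, 1))
  b <- mkAxis(c(18, 0, 0), c(0, 1, 0))
  ap <- closestApproach(a, b)
  expect_equal(ap$distance, 18)
  expect_false(ap$parallel)
  same <- closestApproach(a, mkAxis(c(0, 0, 0), c(0, 0, 1)))
  expect_true(same$parallel)
  expect_equal(same$distance, 0)
  expect_error(closestApproach(a, mkAxis(c(1, 0, 0), c(0, 0, 1),
                                         ext = c(0, 0))), "zero-length")
})

test_that("closest approach matches a refined brute-force sampling oracle", {
  for (s in 1:60) {
    set.seed(s)
    p1 <- rnorm(3, sd = 15); p2 <- rnorm(3, sd = 15)
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    e1 <- sort(runif(2, -25, 25)); e2 <- sort(runif(2, -25, 25))
    if (diff(e1) < 1 || diff(e2) < 1) next
    a <- mkAxis(p1, u1, e1); b <- mkAxis(p2, u2, e2)
    ap <- closestApproach(a, b)
    oracle <- bruteSegmentDistance(p1, u1, e1, p2, u2, e2)
    expect_equal(ap$distance, oracle, tolerance = 1e-4)
  }
})

test_that("the signed crossing angle reproduces constructed chirality", {
  cr <- buildCrossover(60, 18)
  expect_equal(measureAlpha(cr$atoms), 60, tolerance = 1e-9)
  ## mirror image: chirality antisymmetry under an improper isometry
  expect_equal(measureAlpha(mirrorAssembly(cr$atoms)), -60, tolerance = 1e-9)
  ## calibration anchor: the right-handed groove-backbone construct (the
  ## backbone of one helix laid along the major groove of the other, the
  ## self-fitted mode of right-handed crossovers) must come out positive
  gb <- buildCrossover(60, 18, mode = "groove_backbone_major")
  cx <- findCrossovers(list(gb$duplexA, gb$duplexB))[[1]]
  expect_identical(handedness(cx), "right")
  expect_identical(contactMode(classifyMode(cx)), "MAJOR_GROOVE_BACKBONE")
  expect_gt(alphaDeg(cx), 0)
})

test_that("degenerate crossing-angle inputs error out", {
  a <- mkAxis(c(0, 0, 0), c(0, 0, 1))
  b <- mkAxis(c(0, 0, 0), c(0, 1, 1))
  expect_error(signedCrossingAngle(a, b), "coincident|undefined")
})

test_that("exact 90-degree crossings fold to +90", {
  cr <- buildCrossover(90, 18)
  expect_equal(measureAlpha(cr$atoms), 90, tolerance = 1e-9)
})

test_that("alpha is invariant under proper rigid motions, exchange-symmetric,
           and bounded by 90 degrees", {
  cr <- buildCrossover(-47.3, 19.5)
  base <- measureAlpha(cr$atoms)
  expect_equal(base, -47.3, tolerance = 1e-9)
  for (s in 1:6) {
    tr <- randomRigid(100 + s)
    expect_equal(measureAlpha(applyRigidAtoms(cr$atoms, tr)), base,
                 tolerance = 1e-9)
  }
  dups <- duplexesFromAtoms(cr$atoms)
  fa <- fitLinearAxis(dups[[1]]); fb <- fitLinearAxis(dups[[2]])
  expect_equal(signedCrossingAngle(fa, fb), signedCrossingAngle(fb, fa),
               tolerance = 1e-12)
  for (s in 1:25) {
    set.seed(s)
    a <- mkAxis(rnorm(3, sd = 10), rnorm(3))
    b <- mkAxis(rnorm(3, sd = 10) + c(30, 0, 0), rnorm(3))
    ap <- closestApproach(a, b)
    if (ap$parallel || ap$distance < 1e-6) next
    expect_lte(abs(signedCrossingAngle(a, b, ap)), 90)
  }
})

test_that("findCrossovers applies distance and overlap gates", {
  d1 <- buildIdealBDNA("ACGTACGTACGT")
  at <- atoms(d1)
  at$chain <- ifelse(at$chain == "A", "C", "D")
  far <- at; far$x <- far$x + 40
  d2 <- makeDuplex(far[far$chain == "C", ], far[far$chain == "D", ])
  expect_length(findCrossovers(list(d1, d2)), 0)
  cr <- buildCrossover(60, 18)
  cxs <- findCrossovers(list(cr$duplexA, cr$duplexB))
  expect_length(cxs, 1)
  expect_equal(alphaDeg(cxs[[1]]), 60, tolerance = 1e-9)
  expect_equal(interaxialDistance(cxs[[1]]), 18, tolerance = 1e-9)
})
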