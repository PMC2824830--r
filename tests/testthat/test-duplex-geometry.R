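test_that("an ideal 12-mer yields 12 Watson-Crick pairs in strand-I order", {
  d <- buildIdealBDNA("ACGTACGTACGT")
  at <- atoms(d)
  bp <- detectBasePairs(at[at$chain == "A", ], at[at$chain == "B", ])
  expect_identical(nrow(bp), 12L)
  expect_identical(bp$resiI, 1:12)
  expect_true(all(bp$type == "WC"))
  expect_identical(paste(bp$baseI, collapse = ""), "ACGTACGTACGT")
})

test_that("strands separated beyond the pairing cutoff give no pairs", {
  d <- buildIdealBDNA("ACGTACGTACGT")
  at <- atoms(d)
  b <- at[at$chain == "B", ]
  b$x <- b$x + 30
  expect_identical(nrow(detectBasePairs(at[at$chain == "A", ], b)), 0L)
})

test_that("base-pair frames obey the groove-side definitions", {
  d <- buildIdealBDNA("GCGCGCGC")
  at <- atoms(d)
  ## pair 1: G(A1) . C(B8)
  resI <- at[at$chain == "A" & at$resi == 1, ]
  resII <- at[at$chain == "B" & at$resi == 8, ]
  f <- basePairFrame(resI, resII)
  n4 <- as.numeric(resII[resII$name == "N4", c("x", "y", "z")])
  o2 <- as.numeric(resII[resII$name == "O2", c("x", "y", "z")])
  expect_gt(sum(f$x * (n4 - f$origin)), 0)   # N4 on the major side
  expect_lt(sum(f$x * (o2 - f$origin)), 0)   # O2 on the minor side
  ## frame is orthonormal
  B <- rbind(f$x, f$y, f$z)
  expect_equal(B %*% t(B), diag(3), tolerance = 1e-9)
  ## missing ring atoms give a frame error naming the residue
  expect_error(basePairFrame(resI[resI$name == "C1'", , drop = FALSE], resII),
               "frame error")
})

test_that("frames are orthonormal under noise and track the build twist", {
  for (s in 1:5) {
    d <- buildIdealBDNA("ACGTACGTACGT", noiseSigma = 0.1, seed = s)
    n <- nPairs(d)
    for (i in seq_len(n)) {
      B <- rbind(d@xAxes[i, ], d@yAxes[i, ], d@zAxes[i, ])
      expect_equal(B %*% t(B), diag(3), tolerance = 1e-9)
    }
  }
  ## noiseless: successive z axes agree and x rotates by the build twist
  for (tw in c(34, 36)) {
    d <- buildIdealBDNA("ACGTACGTACGT", twist = tw)
    n <- nPairs(d)
    for (i in seq_len(n - 1)) {
      zAngle <- acos(min(1, sum(d@zAxes[i, ] * d@zAxes[i + 1, ]))) * 180 / pi
      expect_lt(zAngle, 2)
      rot <- atan2(sum(d@xAxes[i + 1, ] * d@yAxes[i, ]),
                   sum(d@xAxes[i + 1, ] * d@xAxes[i, ])) * 180 / pi
      expect_equal(rot, tw, tolerance = 0.5)
    }
  }
})

test_that("collinear origins give an exact axis with zero rmsd", {
  orig <- cbind(0, 0, seq(0, by = 3.38, length.out = 10))
  fit <- fitLinearAxis(orig)
  expect_equal(axisDirection(fit), c(0, 0, 1))
  expect_identical(axisRmsd(fit), 0)
  expect_false(curvatureFlag(fit))
  expect_error(fitLinearAxis(matrix(1, 5, 3)), "degenerate")
})

test_that("the fitted axis matches the builder ground truth", {
  d <- buildIdealBDNA("ACCGGCGCCACA")
  gt <- attr(d, "groundTruth")
  fit <- fitLinearAxis(d)
  expect_gte(abs(sum(axisDirection(fit) * gt$direction)), 0.9999)
  expect_lt(axisRmsd(fit), 0.5)
})

test_that("a circular arc trips the curvature flag at the analytic rmsd", {
  ## 90-degree arc, radius 50: analytic oracle. By symmetry the TLS line is
  ## the chord direction through the centroid, so the rmsd is the population
  ## sd of the sagitta coordinate.
  R <- 50
  theta <- seq(45, 135, length.out = 12) * pi / 180
  orig <- cbind(R * cos(theta), R * sin(theta), 0)
  y <- R * sin(theta)
  rmsdOracle <- sqrt(mean((y - mean(y))^2))
  fit <- fitLinearAxis(orig)
  expect_equal(axisRmsd(fit), rmsdOracle, tolerance = 1e-9)
  expect_true(curvatureFlag(fit))
  expect_gt(rmsdOracle, 2)   # sanity: far above the curvature threshold
})

test_that("axis fitting is equivariant under rigid motions", {
  d <- buildIdealBDNA("ACGTACGTAC", noiseSigma = 0.2, seed = 3)
  fit <- fitLinearAxis(d)
  for (s in 1:8) {
    tr <- randomRigid(s)
    at <- applyRigidAtoms(atoms(d), tr)
    d2 <- makeDuplex(at[at$chain == "A", ], at[at$chain == "B", ])
    fit2 <- fitLinearAxis(d2)
    expect_equal(axisDirection(fit2), as.numeric(tr$rot %*% axisDirection(fit)),
                 tolerance = 1e-9)
    expect_equal(axisPoint(fit2),
                 as.numeric(tr$rot %*% axisPoint(fit) + tr$trans),
                 tolerance = 1e-9)
    expect_equal(axisRmsd(fit2), axisRmsd(fit), tolerance = 1e-9)
  }
})

test_that("swapping strand roles flips direction and y but not x", {
  d <- buildIdealBDNA("ACGTACGTAC")
  at <- atoms(d)
  d2 <- makeDuplex(at[at$chain == "B", ], at[at$chain == "A", ])
  n <- nPairs(d)
  expect_equal(axisDirection(fitLinearAxis(d2)),
               -axisDirection(fitLinearAxis(d)), tolerance = 1e-9)
  for (i in seq_len(n)) {
    j <- n + 1 - i   # pair order reverses with the strand roles
    expect_equal(d2@origins[j, ], d@origins[i, ], tolerance = 1e-9)
    expect_equal(d2@yAxes[j, ], -d@yAxes[i, ], tolerance = 1e-9)
    expect_equal(d2@zAxes[j, ], -d@zAxes[i, ], tolerance = 1e-9)
    expect_equal(d2@xAxes[j, ], d@xAxes[i, ], tolerance = 1e-9)
  }
})

test_that("axis rmsd shrinks with the builder noise level", {
  mean_rmsd <- function(sig) {
    mean(vapply(1:10, function(s) {
      axisRmsd(fitLinearAxis(buildIdealBDNA("ACGTACGTACGT",
                                            noiseSigma = sig, seed = s)))
    }, numeric(1)))
  }
  m0 <- mean_rmsd(0); m2 <- mean_rmsd(0.2); m5 <- mean_rmsd(0.5)
  expect_lt(m0, 1e-9)
  expect_lt(m0, m2)
  expect_lt(m2, m5)
})
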