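test_that("groove sectors partition the circle around each base pair", {
  d <- buildIdealBDNA("ACCGGCGCCACA")
  mid <- nPairs(d) %/% 2
  o <- pairOrigins(d)[mid, ]
  px <- o + 8 * d@xAxes[mid, ]
  gs <- grooveSector(px, d)
  expect_identical(gs$sector, "major")
  expect_equal(gs$radial, 8, tolerance = 1e-6)
  expect_identical(grooveSector(o - 8 * d@xAxes[mid, ], d)$sector, "minor")
  ## every in-plane angle falls in exactly one sector
  fit <- fitLinearAxis(d)
  for (th in seq(-179, 180, by = 7.3)) {
    p <- o + 8 * (cos(th * pi / 180) * d@xAxes[mid, ] +
                    sin(th * pi / 180) * d@yAxes[mid, ])
    sec <- grooveSector(p, d, fit = fit)$sector
    expected <- if (abs(th) <= 60) "major"
      else if (abs(th) >= 120) "minor" else "backbone_side"
    expect_identical(sec, expected)
  }
  ## a point beyond the duplex end is flagged out of range
  far <- pairOrigins(d)[nPairs(d), ] + 10 * axisDirection(fit)
  expect_true(grooveSector(far, d)$outOfRange)
})

test_that("a duplex's own cytosine N4 atoms sit in its major groove", {
  for (s in 1:5) {
    d <- buildIdealBDNA("ACCGGCGCCACA", noiseSigma = 0.15, seed = s)
    a <- atoms(d)
    n4 <- a[a$name == "N4", ]
    secs <- vapply(seq_len(nrow(n4)), function(i) {
      grooveSector(as.numeric(n4[i, c("x", "y", "z")]), d)$sector
    }, character(1))
    expect_gte(mean(secs == "major"), 0.95)
  }
})

test_that("pose templates classify to their designed interaction mode", {
  cases <- list(
    list("groove_backbone_major", 60, 18, "MAJOR_GROOVE_BACKBONE"),
    list("groove_groove_major", -60, 20, "MAJOR_MAJOR"),
    list("groove_groove_minor", -60, 20, "MINOR_MINOR"))
  for (cs in cases) {
    cr <- buildCrossover(cs[[2]], cs[[3]], mode = cs[[1]])
    cx <- findCrossovers(list(cr$duplexA, cr$duplexB))[[1]]
    rp <- classifyMode(cx)
    expect_identical(contactMode(rp), cs[[4]])
    if (cs[[4]] == "MAJOR_GROOVE_BACKBONE") {
      expect_gt(nrow(rp@penetratingPhosphates), 0)
    } else {
      expect_identical(nrow(rp@penetratingPhosphates), 0L)
    }
  }
})

test_that("mode survives rigid motion and duplex exchange", {
  cr <- buildCrossover(55, 17, mode = "groove_backbone_major")
  cx <- findCrossovers(list(cr$duplexA, cr$duplexB))[[1]]
  expect_identical(contactMode(classifyMode(cx)), "MAJOR_GROOVE_BACKBONE")
  for (s in 1:4) {
    at <- applyRigidAtoms(cr$atoms, randomRigid(200 + s))
    dups <- duplexesFromAtoms(at)
    cx2 <- findCrossovers(dups)[[1]]
    expect_identical(contactMode(classifyMode(cx2)), "MAJOR_GROOVE_BACKBONE")
  }
  cxSwap <- findCrossovers(list(cr$duplexB, cr$duplexA))[[1]]
  expect_identical(contactMode(classifyMode(cxSwap)), "MAJOR_GROOVE_BACKBONE")
})

test_that("anchor distance windows match the bold / bold-italic criteria", {
  rp30 <- withAnchorAt(3.0)
  expect_identical(sum(rp30@anchors$kind == "hbond_anchor"), 1L)
  expect_equal(min(rp30@anchors$distance), 3.0, tolerance = 1e-9)
  rp40 <- withAnchorAt(4.0)
  expect_identical(sum(rp40@anchors$kind == "proximal_anchor"), 1L)
  expect_identical(sum(rp40@anchors$kind == "hbond_anchor"), 0L)
  rp50 <- withAnchorAt(5.0)
  expect_identical(nrow(rp50@anchors), 0L)
  ## the (3.4, 3.5) gap is a no-man's land: neither category
  rp345 <- withAnchorAt(3.45)
  expect_identical(nrow(rp345@anchors), 0L)
  ## the two anchor classes are disjoint by construction
  expect_identical(
    intersect(rp30@anchors$kind, c("proximal_anchor")), character(0))
})

test_that("groove-groove crossovers carry no sequence-specific anchors", {
  cr <- buildCrossover(-60, 20, mode = "groove_groove_major")
  cx <- findCrossovers(list(cr$duplexA, cr$duplexB))[[1]]
  rp <- detectAnchorContacts(classifyMode(cx))
  expect_identical(nrow(rp@anchors), 0L)
})

mkIon <- function(x, y, z, resn = "MG", el = "Mg", divalent = TRUE) {
  data.frame(record = "HETATM", serial = 9000L, name = resn, altloc = "",
             resn = resn, chain = "M", resi = 1L, icode = "", x = x, y = y,
             z = z, occ = 1, element = el, divalent = divalent,
             stringsAsFactors = FALSE)
}

test_that("cation bridges require contacts to both duplexes", {
  cr <- buildCrossover(60, 17, mode = "groove_backbone_major")
  cx <- findCrossovers(list(cr$duplexA, cr$duplexB))[[1]]
  rp <- classifyMode(cx)
  ## nearest inter-duplex atom pair; drop an Mg at its midpoint
  xa <- xyzOf(cx@duplexA@atoms); xb <- xyzOf(cx@duplexB@atoms)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  idx <- arrayInd(which.min(d2), dim(d2))
  mid <- (xa[idx[1], ] + xb[idx[2], ]) / 2
  gap <- sqrt(min(d2))
  expect_lt(gap, 8)   # the contact is tight enough to bridge
  ion <- mkIon(mid[1], mid[2], mid[3])
  rp1 <- detectCationBridges(rp, ion)
  expect_identical(nrow(cationBridges(rp1)), 1L)
  expect_true(cationBridges(rp1)$divalent)
  ## one-sided ion: 2.1 A from duplex A only
  far <- xa[1, ] + c(2.1, 0, 0)
  rp2 <- detectCationBridges(rp, mkIon(far[1], far[2], far[3]))
  expect_identical(nrow(cationBridges(rp2)), 0L)
  ## a bridging sodium is listed but flagged non-divalent
  na <- mkIon(mid[1], mid[2], mid[3], resn = "NA", el = "Na",
              divalent = FALSE)
  rp3 <- detectCationBridges(rp, na)
  expect_identical(nrow(cationBridges(rp3)), 1L)
  expect_false(cationBridges(rp3)$divalent)
})
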