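## shared fixture helpers; everything is generated in code, no stored data

xyzOf <- function(df) cbind(df$x, df$y, df$z)

## a small random rigid (proper) transform, reproducible by seed
randomRigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(rot = R, trans = rnorm(3, sd = 20))
}

applyRigidAtoms <- function(atoms, tr) {
  m <- xyzOf(atoms) %*% t(tr$rot)
  atoms$x <- m[, 1] + tr$trans[1]
  atoms$y <- m[, 2] + tr$trans[2]
  atoms$z <- m[, 3] + tr$trans[3]
  atoms
}

## rebuild the two duplexes of a buildCrossover() atom table (chains A/B and
## C/D), e.g. after mirroring or a rigid motion
duplexesFromAtoms <- function(at) {
  list(
    suppressWarnings(makeDuplex(at[at$chain == "A", ], at[at$chain == "B", ],
                                source = list(label = "AB"))),
    suppressWarnings(makeDuplex(at[at$chain == "C", ], at[at$chain == "D", ],
                                source = list(label = "CD"))))
}

measureAlpha <- function(at) {
  dups <- duplexesFromAtoms(at)
  cx <- findCrossovers(dups, maxDistance = 30)
  stopifnot(length(cx) == 1)
  alphaDeg(cx[[1]])
}

## independent brute-force oracle: minimum distance between two segments by
## recursive grid refinement (no closed-form geometry shared with the
## implementation)
bruteSegmentDistance <- function(p1, u1, e1, p2, u2, e2,
                                 n = 60, rounds = 4) {
  lo1 <- e1[1]; hi1 <- e1[2]; lo2 <- e2[1]; hi2 <- e2[2]
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    s1 <- seq(lo1, hi1, length.out = n)
    s2 <- seq(lo2, hi2, length.out = n)
    a <- outer(s1, rep(1, n))
    b <- outer(rep(1, n), s2)
    d2 <- 0
    for (k in 1:3) {
      q <- (p1[k] + a * u1[k]) - (p2[k] + b * u2[k])
      d2 <- d2 + q * q
    }
    idx <- arrayInd(which.min(d2), dim(d2))
    best <- c(s1[idx[1]], s2[idx[2]])
    w1 <- (hi1 - lo1) / (n - 1); w2 <- (hi2 - lo2) / (n - 1)
    lo1 <- max(e1[1], best[1] - w1); hi1 <- min(e1[2], best[1] + w1)
    lo2 <- max(e2[1], best[2] - w2); hi2 <- min(e2[2], best[2] + w2)
  }
  q1 <- p1 + best[1] * u1
  q2 <- p2 + best[2] * u2
  sqrt(sum((q1 - q2)^2))
}

## brute-force lattice-contact oracle for a P1 cell: count shifts in
## [-3,3]^3 placing any atom within `radius` of the reference copy
bruteP1Copies <- function(model, radius) {
  M <- orthogonalizationMatrix(unitCell(model))
  at <- atoms(model)
  ref <- xyzOf(at)
  count <- 0L
  for (u in -3:3) for (v in -3:3) for (w in -3:3) {
    t <- as.numeric(M %*% c(u, v, w))
    moved <- sweep(ref, 2, t, "+")
    if (u == 0 && v == 0 && w == 0) { count <- count + 1L; next }
    d2min <- Inf
    for (k in seq_len(nrow(moved))) {
      d2 <- (ref[, 1] - moved[k, 1])^2 + (ref[, 2] - moved[k, 2])^2 +
        (ref[, 3] - moved[k, 3])^2
      d2min <- min(d2min, min(d2))
      if (d2min <= radius^2) break
    }
    if (d2min <= radius^2) count <- count + 1L
  }
  count
}

expectModeOf <- c(groove_backbone_major = "MAJOR_GROOVE_BACKBONE",
                  groove_groove_major = "MAJOR_MAJOR",
                  groove_groove_minor = "MINOR_MINOR")

## template-conditional feasible separation (see the methods vignette)
drawDistance <- function(mode) {
  switch(mode,
         groove_backbone_major = runif(1, 15, 18.5),
         groove_groove_major = runif(1, 19, 25),
         groove_groove_minor = runif(1, 19, 25),
         runif(1, 14, 25))
}

## place a cytosine N4 of the penetrated duplex at an exact distance from
## the penetrating phosphate's nearest oxygen and re-run anchor detection.
## Returns the ContactReport together with the identity of the moved base.
withAnchorAt <- function(dist) {
  cr <- buildCrossover(60, 17, mode = "groove_backbone_major")
  cx <- findCrossovers(list(cr$duplexA, cr$duplexB))[[1]]
  rp <- classifyMode(cx)
  stopifnot(nrow(rp@penetratingPhosphates) > 0)
  ph <- rp@penetratingPhosphates[1, ]
  donorDup <- if (ph$donorDuplex == "A") cx@duplexA else cx@duplexB
  target <- if (ph$donorDuplex == "A") "B" else "A"
  phosRes <- donorDup@atoms[donorDup@atoms$chain == ph$chain &
                              donorDup@atoms$resi == ph$resi, ]
  o2p <- as.numeric(phosRes[phosRes$name == "O2P", c("x", "y", "z")])
  p <- as.numeric(phosRes[phosRes$name == "P", c("x", "y", "z")])
  ## approach radially away from the phosphorus, so O2P stays the nearest
  ## phosphate-group atom
  u <- (o2p - p) / sqrt(sum((o2p - p)^2))
  tgtDup <- if (target == "A") cx@duplexA else cx@duplexB
  at <- tgtDup@atoms
  n4idx <- which(at$name == "N4")[1]
  moved <- list(chain = at$chain[n4idx], resi = at$resi[n4idx])
  at[n4idx, c("x", "y", "z")] <- as.list(o2p + dist * u)
  if (target == "A") cx@duplexA@atoms <- at else cx@duplexB@atoms <- at
  rp <- detectAnchorContacts(classifyMode(cx))
  rp@anchors <- rp@anchors[rp@anchors$baseChain == moved$chain &
                             rp@anchors$baseResi == moved$resi, ,
                           drop = FALSE]
  rp
}
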