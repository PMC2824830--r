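#' @include contact-classification.R
NULL

## ------------------------------------------------------------------
## Idealized base-pair templates
##
## Bases are built analytically: rings as regular polygons (bond 1.39 A),
## exocyclic substituents along the external bisector, the pair assembled
## so that the purine N1 / pyrimidine N3 hydrogen bond is 2.9 A, the
## glycosidic N-C1' bonds are 1.47 A and the C1'-C1' distance is 9.4 A.
## The pair frame has its origin at the C1'-C1' midpoint, x towards the
## major-groove edge, y along C1'(I)->C1'(II), z normal to the base plane.
## Backbone atoms are placed on the B-DNA phosphate cylinder (P radius
## 8.9 A) at fixed cylindrical offsets. This is a fiber-model idealization:
## geometrically self-consistent, not a refined nucleotide geometry.
## ------------------------------------------------------------------

.hexRing <- function(bond = 1.39) {
  ang <- .rad(90 - 60 * (0:5))
  m <- cbind(bond * cos(ang), bond * sin(ang))
  rownames(m) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  m
}

## fuse the imidazole ring across the C4-C5 edge, on the far side of ctr
.fusePentagon <- function(p4, p5) {
  e <- p5 - p4
  L <- sqrt(sum(e^2))
  mid <- (p4 + p5) / 2
  r5 <- L / (2 * sin(.rad(36)))
  h <- sqrt(r5^2 - (L / 2)^2)
  nrm <- c(-e[2], e[1]) / L
  ctr <- mid + h * nrm
  if (sum(ctr^2) < sum((mid - h * nrm)^2)) ctr <- mid - h * nrm
  angC4 <- atan2(p4[2] - ctr[2], p4[1] - ctr[1])
  angC5 <- atan2(p5[2] - ctr[2], p5[1] - ctr[1])
  d <- (angC5 - angC4) %% (2 * pi)
  step <- if (abs(d - .rad(72)) < abs(d - (2 * pi - .rad(72)))) .rad(72) else -.rad(72)
  ang <- angC4 - step * (1:3)           # long way round: C4,N9,C8,N7,C5
  v <- cbind(ctr[1] + r5 * cos(ang), ctr[2] + r5 * sin(ang))
  rownames(v) <- c("N9", "C8", "N7")
  v
}

.exoAtom <- function(ring, i, bond = 1.35) {
  n <- nrow(ring)
  a <- ring[(i - 2) %% n + 1, ]
  b <- ring[i %% n + 1, ]
  x <- ring[i, ]
  u <- (x - a) / sqrt(sum((x - a)^2)) + (x - b) / sqrt(sum((x - b)^2))
  x + bond * u / sqrt(sum(u^2))
}

.purine2D <- function(base) {
  hx <- .hexRing()
  at <- rbind(hx, .fusePentagon(hx["C4", ], hx["C5", ]))
  if (base == "A") at <- rbind(at, N6 = .exoAtom(hx, 6))
  if (base == "G") at <- rbind(at, O6 = .exoAtom(hx, 6), N2 = .exoAtom(hx, 2))
  if (base == "I") at <- rbind(at, O6 = .exoAtom(hx, 6))
  at
}

.pyrimidine2D <- function(base) {
  hx <- .hexRing()
  at <- rbind(hx, O2 = .exoAtom(hx, 2))
  if (base == "C") at <- rbind(at, N4 = .exoAtom(hx, 4))
  if (base %in% c("T", "U")) at <- rbind(at, O4 = .exoAtom(hx, 4))
  if (base == "T") at <- rbind(at, C7 = .exoAtom(hx, 5, 1.50))
  at
}

## intersection of two circles, choosing the smaller-x solution
.circleMeet <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  if (h2 < -1e-9) stop("template geometry infeasible")
  h <- sqrt(max(h2, 0))
  u <- (c2 - c1) / d
  m <- c1 + a * u
  nrm <- c(-u[2], u[1])
  p1 <- m + h * nrm
  p2 <- m - h * nrm
  if (p1[1] < p2[1]) p1 else p2
}

## rigid 2D placement: anchor atom a1 exactly at t1, atom a2 along t1->t2;
## of the two chiral branches keep the one with checkAtom on checkSign x-side
.placeRing2D <- function(at, a1, a2, t1, t2, checkAtom, checkSign) {
  rot2 <- function(th) matrix(c(cos(th), -sin(th), sin(th), cos(th)),
                              2, 2, byrow = TRUE)
  tgt <- atan2(t2[2] - t1[2], t2[1] - t1[1])
  fit <- function(m) {
    v <- m[a2, ] - m[a1, ]
    th <- tgt - atan2(v[2], v[1])
    X <- t(rot2(th) %*% t(m))
    sweep(X, 2, X[a1, ] - t1, "-")
  }
  X <- fit(at)
  if (checkSign * X[checkAtom, 1] > 0) return(X)
  fit(at %*% diag(c(1, -1)))
}

## backbone template, cylindrical (radius A, azimuth deg, z A), strand I
.backboneCyl <- list(
  P    = c(8.90, -108, -2.10),
  O5p  = c(8.30, -104, -1.55),
  C5p  = c(7.80, -100, -1.10),
  C4p  = c(7.20,  -95, -0.80),
  O4p  = c(6.00,  -92, -0.30),
  C3p  = c(7.60,  -92, -0.10),
  O3p  = c(8.70,  -80,  0.60),
  C2p  = c(6.30,  -86, -0.20))

.cyl2cart <- function(v) c(v[1] * cos(.rad(v[2])), v[1] * sin(.rad(v[2])), v[3])

.backboneXYZ <- local({
  done <- NULL
  function() {
    if (!is.null(done)) return(done)
    nm <- c(P = "P", O5p = "O5'", C5p = "C5'", C4p = "C4'", O4p = "O4'",
            C3p = "C3'", O3p = "O3'", C2p = "C2'")
    m <- t(vapply(.backboneCyl, .cyl2cart, numeric(3)))
    rownames(m) <- nm[rownames(m)]
    ## free phosphate oxygens point outward, splayed along z
    p <- m["P", ]
    radial <- c(p[1], p[2], 0) / sqrt(p[1]^2 + p[2]^2)
    o1 <- p + 1.48 * .unit(radial + c(0, 0, 0.8))
    o2 <- p + 1.48 * .unit(radial - c(0, 0, 0.8))
    done <<- rbind(m, "O1P" = o1, "O2P" = o2)
    done
  }
})

.tmplEnv <- new.env(parent = emptyenv())

## full heavy-atom template of one pair, keyed by the strand-I letter.
## Returns list(I = matrix, II = matrix) of named atom coordinates (3D, pair
## frame): base + C1' + backbone for each strand.
.pairTemplate <- function(letter) {
  key <- letter
  if (!is.null(.tmplEnv[[key]])) return(.tmplEnv[[key]])
  pu <- letter %in% .purineBases
  purLetter <- if (pu) letter else .wcPartner[[letter]]
  pyrLetter <- if (pu) .wcPartner[[letter]] else letter
  c1c1 <- 9.4
  c1I <- c(0, -c1c1 / 2)
  c1II <- c(0, +c1c1 / 2)
  w1 <- c(0.5, -1.45)    # purine N1 (WC edge)
  w2 <- c(0.5, +1.45)    # pyrimidine N3
  pur2 <- .purine2D(purLetter)
  pyr2 <- .pyrimidine2D(pyrLetter)
  n9 <- .circleMeet(w1, sqrt(sum((pur2["N9", ] - pur2["N1", ])^2)), c1I, 1.47)
  PUR <- .placeRing2D(pur2, "N1", "N9", w1, n9, "N7", +1)
  n1 <- .circleMeet(w2, sqrt(sum((pyr2["N1", ] - pyr2["N3", ])^2)), c1II, 1.47)
  PYR <- .placeRing2D(pyr2, "N3", "N1", w2, n1, "O2", -1)
  to3 <- function(m) cbind(m, 0)
  bbI <- .backboneXYZ()
  bbII <- bbI %*% diag(c(1, -1, -1))      # pair dyad: y -> -y, z -> -z
  rownames(bbII) <- rownames(bbI)
  strandPur <- rbind(to3(PUR), "C1'" = c(c1I, 0))
  strandPyr <- rbind(to3(PYR), "C1'" = c(c1II, 0))
  if (pu) {
    out <- list(I = rbind(strandPur, bbI), II = rbind(strandPyr, bbII),
                baseI = purLetter, baseII = pyrLetter)
  } else {
    ## strand I holds the pyrimidine: apply the dyad to the whole pair
    dy <- function(m) {
      r <- m %*% diag(c(1, -1, -1)); rownames(r) <- rownames(m); r
    }
    out <- list(I = rbind(dy(strandPyr), bbI), II = rbind(dy(strandPur), bbII),
                baseI = pyrLetter, baseII = purLetter)
  }
  .tmplEnv[[key]] <- out
  out
}

.resnOf <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "DU", I = "DI")

## ------------------------------------------------------------------
## builders
## ------------------------------------------------------------------

.seededNoise <- function(n, sd, seed) {
  if (sd <= 0) return(numeric(n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  stats::rnorm(n, sd = sd)
}

#' Build an ideal straight B-DNA duplex
#'
#' Generates a fiber-model duplex along +z: base-pair frames stacked at the
#' given rise and twist, with the antiparallel complementary strand
#' generated automatically and full heavy-atom nucleotides taken from the
#' internal idealized template library. Pair-origin k sits exactly at
#' (0, 0, (k-1) * rise), so the ground-truth helical axis is the +z line
#' through the origin.
#'
#' @param sequence strand-I base string over A, C, G, T (plus U and I for
#'   uracil/inosine).
#' @param twist helical twist per step in degrees (default 36).
#' @param rise helical rise per step in Angstrom (default 3.38).
#' @param noiseSigma isotropic Gaussian coordinate noise, Angstrom
#'   (default 0).
#' @param seed integer seed for the noise (deterministic given
#'   \code{(params, seed)}).
#' @param chainI,chainII chain identifiers (defaults "A"/"B").
#' @return a \code{\link{Duplex}}; attribute \code{groundTruth} carries the
#'   build axis (point, direction), twist and rise for use as an oracle.
#' @examples
#' d <- buildIdealBDNA("CCGCCGGCGG")
#' duplexSequences(d)   # self-complementary
#' @export
buildIdealBDNA <- function(sequence, twist = 36, rise = 3.38,
                           noiseSigma = 0, seed = NULL,
                           chainI = "A", chainII = "B") {
  stopifnot(twist > 20, twist < 45, rise > 2.5, rise < 4.5)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(letters1 %in% names(.wcPartner)))
    stop("unknown base letter(s): ",
         paste(setdiff(letters1, names(.wcPartner)), collapse = ", "))
  n <- length(letters1)
  if (n < 4) stop("sequence must have at least 4 bases")
  rowsI <- list(); rowsII <- list()
  for (k in seq_len(n)) {
    tpl <- .pairTemplate(letters1[k])
    R <- .rotZ(.rad((k - 1) * twist))
    shift <- c(0, 0, (k - 1) * rise)
    place <- function(m) sweep(m %*% t(R), 2, shift, "+")
    mI <- place(tpl$I); mII <- place(tpl$II)
    if (k == 1) mI <- mI[!rownames(mI) %in% c("P", "O1P", "O2P"), , drop = FALSE]
    if (k == n) mII <- mII[!rownames(mII) %in% c("P", "O1P", "O2P"), , drop = FALSE]
    rowsI[[k]] <- data.frame(
      record = "ATOM", serial = 0L, name = rownames(mI), altloc = "",
      resn = .resnOf[[tpl$baseI]], chain = chainI, resi = as.integer(k),
      icode = "",
      x = mI[, 1], y = mI[, 2], z = mI[, 3], occ = 1,
      element = .inferElement(rownames(mI), .resnOf[[tpl$baseI]]),
      stringsAsFactors = FALSE)
    rowsII[[k]] <- data.frame(
      record = "ATOM", serial = 0L, name = rownames(mII), altloc = "",
      resn = .resnOf[[tpl$baseII]], chain = chainII,
      resi = as.integer(n + 1 - k), icode = "", x = mII[, 1], y = mII[, 2], z = mII[, 3], occ = 1,
      element = .inferElement(rownames(mII), .resnOf[[tpl$baseII]]),
      stringsAsFactors = FALSE)
  }
  atomsI <- do.call(rbind, rowsI)
  atomsII <- do.call(rbind, rev(rowsII))      # strand II 5'->3' order
  atoms <- rbind(atomsI, atomsII)
  nz <- .seededNoise(3 * nrow(atoms), noiseSigma, seed)
  if (noiseSigma > 0) {
    atoms$x <- atoms$x + nz[seq_len(nrow(atoms))]
    atoms$y <- atoms$y + nz[nrow(atoms) + seq_len(nrow(atoms))]
    atoms$z <- atoms$z + nz[2 * nrow(atoms) + seq_len(nrow(atoms))]
  }
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  d <- makeDuplex(atoms[atoms$chain == chainI, , drop = FALSE],
                  atoms[atoms$chain == chainII, , drop = FALSE],
                  source = list(label = paste0(chainI, chainII)))
  if (is.null(d)) stop("internal error: ideal duplex failed pair detection")
  attr(d, "groundTruth") <- list(point = c(0, 0, 0), direction = c(0, 0, 1),
                                 twist = twist, rise = rise)
  d
}

## roll angle (about +z) sending azimuth `az` (radians) to target `to`
.rollTo <- function(az, to) to - az

## azimuth of the feature that must face the partner, for a centred duplex
.featureAzimuth <- function(duplex, feature = c("major", "minor", "backbone")) {
  feature <- match.arg(feature)
  mid <- which.min(abs(duplex@origins[, 3]))
  if (feature %in% c("major", "minor")) {
    v <- duplex@xAxes[mid, ]
    az <- atan2(v[2], v[1])
    if (feature == "minor") az <- az + pi
    az
  } else {
    p <- duplex@atoms[duplex@atoms$name == "P", , drop = FALSE]
    stopifnot(nrow(p) > 0)
    k <- which.min(abs(p$z - duplex@origins[mid, 3]))
    atan2(p$y[k], p$x[k])
  }
}

#' Build a posed crossover of two ideal duplexes
#'
#' Duplex A is laid along +z (centred at the origin); duplex B is rotated
#' by \code{alphaDeg} about the x-axis (the inter-axial normal) and
#' translated to \code{distance} along +x. For the mode templates, each
#' duplex is additionally rolled about its own axis so the requested face
#' points at the partner's contact region: A's major (or minor) groove
#' faces B, and B presents its backbone phosphates (groove-backbone
#' template) or the requested groove floor (groove-groove templates). The
#' measured signed crossing angle and interaxial distance equal the
#' requested values to 1e-6.
#'
#' @param alphaDeg requested signed crossing angle, degrees, in (-90, +90].
#' @param distance requested interaxial distance, Angstrom (> 0).
#' @param mode pose template: \code{"none"}, \code{"groove_backbone_major"},
#'   \code{"groove_groove_major"} or \code{"groove_groove_minor"}.
#' @param sequenceA,sequenceB strand-I sequences of the two duplexes.
#' @param twist,rise,noiseSigma,seed passed to \code{\link{buildIdealBDNA}}.
#' @return list with \code{duplexA}, \code{duplexB} (chains A/B and C/D),
#'   \code{atoms} (combined atom table), and \code{spec} (the requested
#'   pose).
#' @examples
#' cr <- buildCrossover(60, 18, mode = "groove_backbone_major")
#' alphaDeg(findCrossovers(list(cr$duplexA, cr$duplexB))[[1]])
#' @export
buildCrossover <- function(alphaDeg, distance,
                           mode = c("none", "groove_backbone_major",
                                    "groove_groove_major",
                                    "groove_groove_minor"),
                           sequenceA = "ACCGGCGCCACA",
                           sequenceB = "ACCGGCGCCACA",
                           twist = 36, rise = 3.38, noiseSigma = 0,
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(alphaDeg > -90 || alphaDeg == 90, alphaDeg <= 90, distance > 0)
  if (mode != "none" && distance < 10)
    warning("distance below 10 A with a groove template: expect clashes")
  dA <- buildIdealBDNA(sequenceA, twist = twist, rise = rise,
                       noiseSigma = noiseSigma, seed = seed,
                       chainI = "A", chainII = "B")
  dB <- buildIdealBDNA(sequenceB, twist = twist, rise = rise,
                       noiseSigma = noiseSigma,
                       seed = if (is.null(seed)) NULL else seed + 1L,
                       chainI = "C", chainII = "D")
  centre <- function(d) {
    ctr <- colMeans(d@origins)
    .transformDuplex(d, diag(3), -ctr)
  }
  dA <- centre(dA); dB <- centre(dB)
  rollA <- switch(mode,
    none = 0,
    groove_backbone_major = .rollTo(.featureAzimuth(dA, "major"), 0),
    groove_groove_major   = .rollTo(.featureAzimuth(dA, "major"), 0),
    groove_groove_minor   = .rollTo(.featureAzimuth(dA, "minor"), 0))
  rollB <- switch(mode,
    none = 0,
    groove_backbone_major = .rollTo(.featureAzimuth(dB, "backbone"), pi),
    groove_groove_major   = .rollTo(.featureAzimuth(dB, "major"), pi),
    groove_groove_minor   = .rollTo(.featureAzimuth(dB, "minor"), pi))
  dA <- .transformDuplex(dA, .rotZ(rollA), c(0, 0, 0),
                         source = list(label = "AB"))
  Rb <- .rotX(.rad(alphaDeg)) %*% .rotZ(rollB)
  dB <- .transformDuplex(dB, Rb, c(distance, 0, 0),
                         source = list(label = "CD"))
  atoms <- rbind(dA@atoms, dB@atoms)
  atoms$serial <- seq_len(nrow(atoms))
  list(duplexA = dA, duplexB = dB, atoms = atoms,
       spec = list(alphaDeg = alphaDeg, distance = distance, mode = mode,
                   sequences = c(sequenceA, sequenceB)))
}

#' Mirror-reflect an assembly through the yz-plane
#'
#' An improper isometry: all interatomic distances are preserved while
#' every signed crossing angle changes sign. Applying it twice restores the
#' original coordinates.
#'
#' @param x an atom data.frame, \code{\link{Duplex}} or
#'   \code{\link{CrystalModel}}.
#' @return the mirrored object (a \code{Duplex} input is re-built from its
#'   mirrored atoms, since frames are chirality-sensitive).
#' @examples
#' cr <- buildCrossover(60, 18)
#' m <- mirrorAssembly(cr$atoms)
#' @export
mirrorAssembly <- function(x) {
  if (is.data.frame(x)) {
    x$x <- -x$x
    return(x)
  }
  if (is(x, "Duplex")) {
    at <- x@atoms
    at$x <- -at$x
    return(makeDuplex(at[at$chain == x@chainI, , drop = FALSE],
                      at[at$chain == x@chainII, , drop = FALSE],
                      source = x@source))
  }
  if (is(x, "CrystalModel")) {
    at <- x@atoms
    at$x <- -at$x
    return(makeCrystalModel(at, cell = x@cell, operators = x@operators))
  }
  stop("cannot mirror object of class ", class(x)[1])
}

#' Write a mock crystal PDB file
#'
#' Places the given atoms as the asymmetric unit of a crystal with the
#' given cell (CRYST1 record, space group from the cell), so that
#' \code{\link{readStructure}} plus \code{\link{expandNeighborhood}}
#' reconstruct the designed packing neighbours.
#'
#' @param x atoms data.frame, a \code{\link{Duplex}}, or a list of duplexes.
#' @param cell a \code{\link{UnitCell}} (its \code{spaceGroup} selects the
#'   operators on re-reading).
#' @param path output PDB path.
#' @param center move the centroid of the atoms to the cell centre
#'   (default TRUE).
#' @return \code{path}, invisibly.
#' @export
makeMockCrystal <- function(x, cell, path, center = TRUE) {
  at <- if (is.data.frame(x)) x
    else if (is(x, "Duplex")) x@atoms
    else if (is.list(x)) do.call(rbind, lapply(x, function(d) d@atoms))
    else stop("unsupported input for makeMockCrystal")
  at$serial <- seq_len(nrow(at))
  M <- orthogonalizationMatrix(cell)
  xyz <- .xyz(at)
  ext <- apply(xyz, 2, max) - apply(xyz, 2, min)
  if (.vnorm(ext) > 4 * max(cell@a, cell@b, cell@c))
    stop("duplex larger than cell: extent ", round(.vnorm(ext), 1),
         " A will not form a sensible lattice")
  if (center) {
    ctr <- as.numeric(M %*% c(0.5, 0.5, 0.5)) - colMeans(xyz)
    at$x <- at$x + ctr[1]; at$y <- at$y + ctr[2]; at$z <- at$z + ctr[3]
  }
  model <- makeCrystalModel(at, cell = cell)
  writeStructure(model, path)
}
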