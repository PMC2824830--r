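#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Unit cell of a crystal
#'
#' Cell edge lengths are in Angstrom, angles in degrees, and the space group
#' is a Hermann-Mauguin symbol (e.g. \code{"P 1"}, \code{"R 3"},
#' \code{"C 1 2 1"}).
#'
#' @slot a,b,c numeric(1), cell edge lengths (Angstrom), all > 0.
#' @slot alpha,beta,gamma numeric(1), cell angles in degrees, in (0, 180).
#' @slot spaceGroup character(1) Hermann-Mauguin symbol.
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 spaceGroup = "character"),
  prototype(a = 1, b = 1, c = 1, alpha = 90, beta = 90, gamma = 90,
            spaceGroup = "P 1"))

setValidity("UnitCell", function(object) {
  msg <- character()
  if (any(c(object@a, object@b, object@c) <= 0))
    msg <- c(msg, "cell lengths must be > 0")
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(ang <= 0 | ang >= 180))
    msg <- c(msg, "cell angles must lie in (0, 180) degrees")
  ca <- cos(.rad(object@alpha)); cb <- cos(.rad(object@beta))
  cg <- cos(.rad(object@gamma))
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (!is.finite(v2) || v2 <= 0)
    msg <- c(msg, "cell is degenerate (non-positive volume)")
  if (length(msg)) msg else TRUE
})

#' Crystallographic symmetry operator
#'
#' A rotation matrix and translation vector acting on fractional coordinates,
#' together with the conventional "xyz-triplet" label (e.g.
#' \code{"-y,x-y,z+1/3"}).
#'
#' @slot rot 3x3 numeric matrix in the fractional frame, det = +/- 1.
#' @slot trans numeric(3), fractional translation.
#' @slot label character(1), xyz-triplet notation.
#' @exportClass SymmetryOperator
setClass("SymmetryOperator",
  representation(rot = "matrix", trans = "numeric", label = "character"),
  prototype(rot = diag(3), trans = c(0, 0, 0), label = "x,y,z"))

setValidity("SymmetryOperator", function(object) {
  if (!all(dim(object@rot) == c(3, 3))) return("rot must be 3x3")
  if (length(object@trans) != 3) return("trans must be length 3")
  if (abs(abs(det(object@rot)) - 1) > 1e-9)
    return("rot must have determinant +/- 1")
  TRUE
})

#' Parsed crystal structure
#'
#' Holds the asymmetric-unit atoms, the unit cell, the space-group symmetry
#' operators, the identities of the nucleic-acid chains and the monoatomic
#' cation sites.
#'
#' Atom tables are data.frames with columns \code{record, serial, name,
#' altloc, resn, chain, resi, icode, x, y, z, occ, element}.
#'
#' @slot atoms data.frame of all ATOM/HETATM records (alt-locs resolved).
#' @slot cell \code{UnitCell} or \code{NULL} when the file has no cell.
#' @slot operators list of \code{SymmetryOperator}.
#' @slot nucleicChains character, chain identifiers holding nucleic acids.
#' @slot ions data.frame subset of \code{atoms}: monoatomic cation sites,
#'   with an extra logical column \code{divalent}.
#' @exportClass CrystalModel
setClass("CrystalModel",
  representation(atoms = "data.frame", cell = "ANY",
                 operators = "list", nucleicChains = "character",
                 ions = "data.frame"))

setValidity("CrystalModel", function(object) {
  msg <- character()
  need <- c("record", "serial", "name", "altloc", "resn", "chain", "resi",
            "icode", "x", "y", "z", "occ", "element")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "atoms is missing required columns")
  if (!is.null(object@cell) && !is(object@cell, "UnitCell"))
    msg <- c(msg, "cell must be a UnitCell or NULL")
  if (nrow(object@ions) && !all(object@ions$serial %in% object@atoms$serial))
    msg <- c(msg, "every ion must also be present in atoms")
  if (nrow(object@atoms) &&
      !all(is.finite(c(object@atoms$x, object@atoms$y, object@atoms$z))))
    msg <- c(msg, "atom positions must be finite")
  if (length(msg)) msg else TRUE
})

#' A symmetry-placed copy of a nucleic chain group
#'
#' @slot chainIds character, source chain identifiers of the copy.
#' @slot operator the generating \code{SymmetryOperator}.
#' @slot shift integer(3) lattice translation (unit-cell multiples).
#' @slot rot,trans the rigid transform in the orthogonal Angstrom frame.
#' @slot atoms transformed atom table.
#' @slot isIdentity logical(1), TRUE for the untransformed asymmetric unit.
#' @exportClass PlacedCopy
setClass("PlacedCopy",
  representation(chainIds = "character", operator = "SymmetryOperator",
                 shift = "integer", rot = "matrix", trans = "numeric",
                 atoms = "data.frame", isIdentity = "logical"))

#' An ordered run of Watson-Crick base pairs with reference frames
#'
#' Pair i has origin (midpoint of the two C1' atoms) \code{origins[i, ]} and
#' an orthonormal right-handed triad: \code{xAxes[i, ]} points towards the
#' major-groove edge, \code{yAxes[i, ]} along C1'(I) -> C1'(II), and
#' \code{zAxes[i, ]} along the strand-I 5'->3' progression.
#'
#' @slot atoms atom table of both strands (nucleic atoms only).
#' @slot pairs data.frame with columns \code{resiI, resiJ, baseI, baseJ, type}.
#' @slot origins,xAxes,yAxes,zAxes n x 3 matrices of frame data.
#' @slot sequenceI,sequenceII character(1) base-letter strings.
#' @slot chainI,chainII character(1) chain ids of strand I and II.
#' @slot source list: provenance (label, operator label, lattice shift).
#' @exportClass Duplex
setClass("Duplex",
  representation(atoms = "data.frame", pairs = "data.frame",
                 origins = "matrix", xAxes = "matrix", yAxes = "matrix",
                 zAxes = "matrix", sequenceI = "character",
                 sequenceII = "character", chainI = "character",
                 chainII = "character", source = "list"))

setValidity("Duplex", function(object) {
  n <- nrow(object@origins)
  if (n < 4) return("a Duplex needs at least 4 base pairs")
  if (nrow(object@pairs) != n) return("pairs and origins disagree in length")
  ok <- vapply(seq_len(n), function(i) {
    x <- object@xAxes[i, ]; y <- object@yAxes[i, ]; z <- object@zAxes[i, ]
    max(abs(c(sum(x * y), sum(x * z), sum(y * z)))) < 1e-6 &&
      max(abs(c(.vnorm(x), .vnorm(y), .vnorm(z)) - 1)) < 1e-6
  }, logical(1))
  if (!all(ok)) return("frame axes must be orthonormal")
  TRUE
})

#' Best linear helical axis of a duplex
#'
#' Total-least-squares line through the base-pair origins; the first
#' principal direction of the centred origin cloud. The direction sign
#' follows the strand-I 5'->3' progression.
#'
#' @slot point numeric(3), centroid of pair origins (on the line).
#' @slot direction unit numeric(3).
#' @slot rmsd RMS distance of origins to the line (Angstrom).
#' @slot curvatureFlag TRUE when rmsd exceeds the curvature threshold.
#' @slot extents numeric(2), range of origin projections along the
#'   direction, relative to \code{point} (defines the fitted segment).
#' @exportClass HelicalAxisFit
setClass("HelicalAxisFit",
  representation(point = "numeric", direction = "numeric", rmsd = "numeric",
                 curvatureFlag = "logical", extents = "numeric"))

setValidity("HelicalAxisFit", function(object) {
  if (abs(.vnorm(object@direction) - 1) > 1e-9)
    return("direction must be unit length")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' A juxtaposed duplex pair with signed crossing angle
#'
#' The crossing angle alpha is the acute angle between the two fitted axes,
#' signed by the handedness of the crossing: positive for right-handed
#' crossovers (clockwise rotation closes the small angle), negative for
#' left-handed ones.
#'
#' @slot duplexA,duplexB the two \code{Duplex} objects.
#' @slot axisA,axisB their \code{HelicalAxisFit}s.
#' @slot closestA,closestB numeric(3) closest-approach points, one per axis.
#' @slot distance numeric(1) interaxial closest-approach distance (Angstrom).
#' @slot alphaDeg signed crossing angle in degrees, in (-90, +90].
#' @slot handedness "right" or "left".
#' @slot lowConfidence TRUE when either axis carries a curvature flag.
#' @exportClass Crossover
setClass("Crossover",
  representation(duplexA = "Duplex", duplexB = "Duplex",
                 axisA = "HelicalAxisFit", axisB = "HelicalAxisFit",
                 closestA = "numeric", closestB = "numeric",
                 distance = "numeric", alphaDeg = "numeric",
                 handedness = "character", lowConfidence = "logical"))

setValidity("Crossover", function(object) {
  if (abs(object@alphaDeg) > 90 + 1e-9)
    return("alphaDeg must lie in (-90, +90]")
  hand <- if (object@alphaDeg >= 0) "right" else "left"
  if (object@handedness != hand)
    return("handedness must equal the sign of alphaDeg")
  if (object@distance < 0) return("distance must be >= 0")
  TRUE
})

#' Classified interaction mode of a crossover
#'
#' @slot crossover the underlying \code{Crossover}.
#' @slot mode one of MAJOR_GROOVE_BACKBONE, MINOR_GROOVE_BACKBONE,
#'   MAJOR_MAJOR, MINOR_MINOR, MAJOR_MINOR, UNCLASSIFIED.
#' @slot penetratingPhosphates data.frame: phosphorus atoms of one duplex
#'   found inside a groove of the other (columns \code{donorDuplex, chain,
#'   resi, groove, radial}).
#' @slot anchors data.frame of amino-group/phosphate anchor contacts.
#' @slot bridges data.frame of cation bridges.
#' @exportClass ContactReport
setClass("ContactReport",
  representation(crossover = "Crossover", mode = "character",
                 penetratingPhosphates = "data.frame",
                 anchors = "data.frame", bridges = "data.frame"))

.contactModes <- c("MAJOR_GROOVE_BACKBONE", "MINOR_GROOVE_BACKBONE",
                   "MAJOR_MAJOR", "MINOR_MINOR", "MAJOR_MINOR",
                   "UNCLASSIFIED")

setValidity("ContactReport", function(object) {
  if (!object@mode %in% .contactModes)
    return(paste("mode must be one of:", paste(.contactModes, collapse = ", ")))
  gb <- object@mode %in% c("MAJOR_GROOVE_BACKBONE", "MINOR_GROOVE_BACKBONE")
  if (gb && nrow(object@penetratingPhosphates) == 0)
    return("groove-backbone modes require >= 1 penetrating phosphate")
  if (!gb && object@mode != "UNCLASSIFIED" &&
      nrow(object@penetratingPhosphates) > 0)
    return("groove-groove modes require 0 penetrating phosphates")
  TRUE
})
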