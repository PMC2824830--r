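#' @include AllGenerics.R
NULL

#' Accessors for structural objects
#'
#' Standard accessor functions for the S4 containers: atom tables, unit
#' cells, symmetry operators, base-pair frames, axis fits and crossover
#' descriptors.
#'
#' @param x an object of the corresponding class.
#' @param ... unused.
#' @return the slot contents (see each class's documentation).
#' @name accessors
#' @aliases atoms unitCell symOperators nucleicChains ions nPairs
#'   pairOrigins duplexSequences axisDirection axisPoint axisRmsd
#'   curvatureFlag alphaDeg handedness interaxialDistance contactMode
#'   anchorContacts cationBridges
#' @examples
#' d <- buildIdealBDNA("ACGTACGTACGT")
#' nPairs(d)
#' duplexSequences(d)
NULL

#' @rdname accessors
#' @export
setMethod("atoms", "CrystalModel", function(x, ...) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Duplex", function(x, ...) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "PlacedCopy", function(x, ...) x@atoms)

#' @rdname accessors
#' @export
setMethod("unitCell", "CrystalModel", function(x) x@cell)

#' @rdname accessors
#' @export
setMethod("symOperators", "CrystalModel", function(x) x@operators)

#' @rdname accessors
#' @export
setMethod("nucleicChains", "CrystalModel", function(x) x@nucleicChains)

#' @rdname accessors
#' @export
setMethod("ions", "CrystalModel", function(x) x@ions)

#' @rdname accessors
#' @export
setMethod("nPairs", "Duplex", function(x) nrow(x@origins))

#' @rdname accessors
#' @export
setMethod("pairOrigins", "Duplex", function(x) x@origins)

#' @rdname accessors
#' @export
setMethod("duplexSequences", "Duplex",
          function(x) c(I = x@sequenceI, II = x@sequenceII))

#' @rdname accessors
#' @export
setMethod("axisDirection", "HelicalAxisFit", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("axisPoint", "HelicalAxisFit", function(x) x@point)

#' @rdname accessors
#' @export
setMethod("axisRmsd", "HelicalAxisFit", function(x) x@rmsd)

#' @rdname accessors
#' @export
setMethod("curvatureFlag", "HelicalAxisFit", function(x) x@curvatureFlag)

#' @rdname accessors
#' @export
setMethod("alphaDeg", "Crossover", function(x) x@alphaDeg)

#' @rdname accessors
#' @export
setMethod("handedness", "Crossover", function(x) x@handedness)

#' @rdname accessors
#' @export
setMethod("interaxialDistance", "Crossover", function(x) x@distance)

#' @rdname accessors
#' @export
setMethod("contactMode", "ContactReport", function(x) x@mode)

#' @rdname accessors
#' @export
setMethod("anchorContacts", "ContactReport", function(x) x@anchors)

#' @rdname accessors
#' @export
setMethod("cationBridges", "ContactReport", function(x) x@bridges)

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  [%s]\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, object@spaceGroup))
})

setMethod("show", "SymmetryOperator", function(object) {
  cat("SymmetryOperator:", object@label, "\n")
})

setMethod("show", "CrystalModel", function(object) {
  cat("CrystalModel with", nrow(object@atoms), "atoms\n")
  if (!is.null(object@cell)) {
    cat("  cell: "); show(object@cell)
  } else cat("  cell: none\n")
  cat("  operators:", length(object@operators),
      " nucleic chains:", paste(object@nucleicChains, collapse = ", "),
      " ions:", nrow(object@ions), "\n")
})

setMethod("show", "Duplex", function(object) {
  cat(sprintf("Duplex %s/%s, %d base pairs\n  I : 5'-%s-3'\n  II: 3'-%s-5'\n",
              object@chainI, object@chainII, nrow(object@origins),
              object@sequenceI,
              paste(rev(strsplit(object@sequenceII, "")[[1]]), collapse = "")))
})

setMethod("show", "HelicalAxisFit", function(object) {
  cat(sprintf("HelicalAxisFit: direction (%.4f, %.4f, %.4f), rmsd %.3f A%s\n",
              object@direction[1], object@direction[2], object@direction[3],
              object@rmsd,
              if (object@curvatureFlag) " [curved]" else ""))
})

setMethod("show", "Crossover", function(object) {
  cat(sprintf("Crossover: alpha = %+.2f deg (%s-handed), interaxial %.2f A\n",
              object@alphaDeg, object@handedness, object@distance))
})

setMethod("show", "ContactReport", function(object) {
  cat(sprintf("ContactReport: %s, alpha %+.1f deg, %d anchor(s), %d bridge(s)\n",
              object@mode, object@crossover@alphaDeg,
              nrow(object@anchors), nrow(object@bridges)))
})
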