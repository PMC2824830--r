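#' @include AllClasses.R
NULL

#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))

#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))

#' @export
setGeneric("symOperators", function(x) standardGeneric("symOperators"))

#' @export
setGeneric("nucleicChains", function(x) standardGeneric("nucleicChains"))

#' @export
setGeneric("ions", function(x) standardGeneric("ions"))

#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @export
setGeneric("pairOrigins", function(x) standardGeneric("pairOrigins"))

#' @export
setGeneric("duplexSequences", function(x) standardGeneric("duplexSequences"))

#' @export
setGeneric("axisDirection", function(x) standardGeneric("axisDirection"))

#' @export
setGeneric("axisPoint", function(x) standardGeneric("axisPoint"))

#' @export
setGeneric("axisRmsd", function(x) standardGeneric("axisRmsd"))

#' @export
setGeneric("curvatureFlag", function(x) standardGeneric("curvatureFlag"))

#' @export
setGeneric("alphaDeg", function(x) standardGeneric("alphaDeg"))

#' @export
setGeneric("handedness", function(x) standardGeneric("handedness"))

#' @export
setGeneric("interaxialDistance", function(x) standardGeneric("interaxialDistance"))

#' @export
setGeneric("contactMode", function(x) standardGeneric("contactMode"))

#' @export
setGeneric("anchorContacts", function(x) standardGeneric("anchorContacts"))

#' @export
setGeneric("cationBridges", function(x) standardGeneric("cationBridges"))

#' @export
setGeneric("fitLinearAxis", function(x, ...) standardGeneric("fitLinearAxis"))
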