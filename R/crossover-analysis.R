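#' @include duplex-geometry.R
NULL

#' Closest approach between two fitted axis segments
#'
#' Standard segment-segment minimum distance over the fitted extents of the
#' two axes. For (anti)parallel axes the overlap-midpoint convention is
#' used and the \code{parallel} flag is set.
#'
#' @param axisA,axisB \code{\link{HelicalAxisFit}} objects.
#' @return list with \code{pointA}, \code{pointB}, \code{distance},
#'   \code{parallel}, and the axial parameters \code{sA}, \code{sB} of the
#'   closest points relative to each axis point.
#' @export
closestApproach <- function(axisA, axisB) {
  pA <- axisA@point; u <- axisA@direction; eA <- axisA@extents
  pB <- axisB@point; v <- axisB@direction; eB <- axisB@extents
  if (diff(eA) <= 0 || diff(eB) <= 0)
    stop("zero-length axis segment")
  w0 <- pA - pB
  a <- 1; b <- sum(u * v); c <- 1
  d <- sum(u * w0); e <- sum(v * w0)
  denom <- a * c - b * b      # = sin^2(angle)
  parallel <- denom < 1e-12
  if (!parallel) {
    sA <- (b * e - c * d) / denom
    sB <- (a * e - b * d) / denom
    sA <- .clamp(sA, eA[1], eA[2])
    ## re-optimise sB for clamped sA, then sA for clamped sB
    sB <- .clamp(sum(v * (pA + sA * u - pB)), eB[1], eB[2])
    sA <- .clamp(sum(u * (pB + sB * v - pA)), eA[1], eA[2])
  } else {
    ## overlap midpoint convention: project B's extents onto A
    tB <- sort(c(sum(u * (pB + eB[1] * v - pA)),
                 sum(u * (pB + eB[2] * v - pA))))
    lo <- max(eA[1], tB[1]); hi <- min(eA[2], tB[2])
    sA <- if (lo <= hi) (lo + hi) / 2 else .clamp((tB[1] + tB[2]) / 2,
                                                  eA[1], eA[2])
    sB <- .clamp(sum(v * (pA + sA * u - pB)), eB[1], eB[2])
  }
  qA <- pA + sA * u
  qB <- pB + sB * v
  list(pointA = qA, pointB = qB, distance = .vnorm(qA - qB),
       parallel = parallel, sA = sA, sB = sB)
}

#' Signed acute crossing angle between two duplex axes
#'
#' The magnitude is the acute angle between the two axis directions
#' (directions are re-signed so their dot product is non-negative). The
#' sign encodes the handedness of the crossing: with \code{u}, \code{v} the
#' acute-folded directions and \code{c} the vector between the closest
#' points (from axis A to axis B), \code{sign(alpha) = sign((u x v) . c)}.
#' This orientation is calibrated so a right-handed groove-backbone
#' self-fitted crossover (the backbone of one helix laid along the major
#' groove of the other) is positive; mirror reflection negates the result.
#' Exact 90-degree crossings are reported as +90.
#'
#' @param axisA,axisB \code{\link{HelicalAxisFit}} objects.
#' @param approach optional result of \code{\link{closestApproach}};
#'   computed when missing.
#' @return signed angle in degrees, in (-90, +90].
#' @examples
#' cr <- buildCrossover(60, 18)
#' signedCrossingAngle(fitLinearAxis(cr$duplexA), fitLinearAxis(cr$duplexB))
#' @export
signedCrossingAngle <- function(axisA, axisB, approach = NULL) {
  if (is.null(approach)) approach <- closestApproach(axisA, axisB)
  cvec <- approach$pointB - approach$pointA
  if (.vnorm(cvec) < 1e-9)
    stop("coincident axes: crossing-angle sign is undefined at zero ",
         "interaxial distance")
  u <- axisA@direction
  v <- axisB@direction
  if (sum(u * v) < 0) v <- -v                     # acute-angle convention
  mag <- .deg(acos(.clamp(sum(u * v), -1, 1)))
  tri <- sum(.cross3(u, v) * cvec)
  s <- sign(tri)
  if (s == 0) s <- 1
  alpha <- s * mag
  if (alpha <= -90 + 1e-9) alpha <- 90            # fold boundary ties to +90
  alpha
}

## provenance label for dedup ordering / reports
.duplexProvenance <- function(duplex) {
  src <- duplex@source
  lab <- if (!is.null(src$label)) src$label else
    paste0(duplex@chainI, duplex@chainII)
  op <- if (!is.null(src$operator)) src$operator else "x,y,z"
  sh <- if (!is.null(src$shift)) paste(src$shift, collapse = ",") else "0,0,0"
  paste0(lab, "|", op, "|", sh)
}

#' Find juxtaposed duplex pairs (crossovers)
#'
#' Emits one \code{\link{Crossover}} per unordered duplex pair whose fitted
#' axes approach within \code{maxDistance} and whose closest points are
#' interior to both fitted segments by at least \code{minOverlap} (one
#' helical rise by default), so that the helices genuinely cross rather
#' than stack end-to-end. Crossovers equivalent under a lattice isometry
#' are collapsed to one representative (smallest provenance). Parallel
#' (zero-angle) juxtapositions are skipped, as the crossing sign is
#' undefined for them.
#'
#' @param duplexes list of \code{\link{Duplex}}.
#' @param maxDistance maximum interaxial distance (default 22 Angstrom).
#' @param minOverlap minimum interior margin of the closest points within
#'   each fitted segment (default 3.4 Angstrom).
#' @param curvatureThreshold passed to \code{\link{fitLinearAxis}}.
#' @param dedup collapse symmetry-equivalent crossovers (default TRUE).
#' @return list of \code{\link{Crossover}}.
#' @export
findCrossovers <- function(duplexes, maxDistance = 22, minOverlap = 3.4,
                           curvatureThreshold = 2, dedup = TRUE) {
  n <- length(duplexes)
  if (n < 2) return(list())
  fits <- lapply(duplexes, fitLinearAxis,
                 curvatureThreshold = curvatureThreshold)
  prov <- vapply(duplexes, .duplexProvenance, character(1))
  out <- list()
  sig <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ## identical placement of the same source duplex is not a crossover
    if (prov[i] == prov[j]) next
    ap <- closestApproach(fits[[i]], fits[[j]])
    if (ap$distance > maxDistance) next
    if (ap$parallel) next
    eA <- fits[[i]]@extents; eB <- fits[[j]]@extents
    if (ap$sA < eA[1] + minOverlap || ap$sA > eA[2] - minOverlap) next
    if (ap$sB < eB[1] + minOverlap || ap$sB > eB[2] - minOverlap) next
    if (ap$distance < 1e-9) next
    alpha <- signedCrossingAngle(fits[[i]], fits[[j]], ap)
    ## order the pair by provenance so reports are deterministic
    if (prov[i] <= prov[j]) { a <- i; b <- j; apo <- ap }
    else {
      a <- j; b <- i
      apo <- list(pointA = ap$pointB, pointB = ap$pointA,
                  distance = ap$distance, parallel = ap$parallel,
                  sA = ap$sB, sB = ap$sA)
    }
    cx <- new("Crossover",
      duplexA = duplexes[[a]], duplexB = duplexes[[b]],
      axisA = fits[[a]], axisB = fits[[b]],
      closestA = apo$pointA, closestB = apo$pointB,
      distance = ap$distance, alphaDeg = alpha,
      handedness = if (alpha >= 0) "right" else "left",
      lowConfidence = fits[[a]]@curvatureFlag || fits[[b]]@curvatureFlag)
    if (dedup) {
      key <- paste(round(alpha, 3), round(ap$distance, 3),
                   paste(sort(round(abs(c(apo$sA, apo$sB)), 1)), collapse = ","))
      hit <- match(key, sig)
      if (!is.na(hit)) {
        ## keep the lexicographically smallest provenance pair
        oldKey <- paste(.duplexProvenance(out[[hit]]@duplexA),
                        .duplexProvenance(out[[hit]]@duplexB))
        newKey <- paste(prov[a], prov[b])
        if (newKey < oldKey) out[[hit]] <- cx
        next
      }
      sig <- c(sig, key)
    }
    out[[length(out) + 1L]] <- cx
  }
  out
}
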