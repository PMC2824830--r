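#' @include crystal-symmetry.R
NULL

## ring atoms used for base-plane fitting
.purineRing <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
.pyrimidineRing <- c("N1", "C2", "N3", "C4", "C5", "C6")

## Watson-Crick complement (I = inosine pairs with C)
.wcPartner <- c(A = "T", T = "A", G = "C", C = "G", U = "A", I = "C")

## per-residue summary used by pair detection
.residueTable <- function(atoms) {
  base <- .baseLetter(atoms$resn)
  keep <- !is.na(base)
  atoms <- atoms[keep, , drop = FALSE]
  base <- base[keep]
  if (!nrow(atoms)) return(NULL)
  key <- paste(atoms$chain, atoms$resi, atoms$icode, sep = "|")
  idx <- split(seq_len(nrow(atoms)), key)
  rows <- lapply(idx, function(ii) {
    sub <- atoms[ii, , drop = FALSE]
    b <- .baseLetter(sub$resn[1])
    pur <- b %in% .purineBases
    ring <- sub[sub$name %in% (if (pur) .purineRing else .pyrimidineRing), ,
                drop = FALSE]
    c1 <- sub[sub$name == "C1'", , drop = FALSE]
    wcName <- if (pur) "N1" else "N3"
    wc <- sub[sub$name == wcName, , drop = FALSE]
    if (!nrow(c1) || !nrow(wc) || nrow(ring) < 4) return(NULL)
    list(chain = sub$chain[1], resi = sub$resi[1], icode = sub$icode[1],
         base = b, purine = pur, c1 = as.numeric(c1[1, c("x", "y", "z")]),
         wc = as.numeric(wc[1, c("x", "y", "z")]),
         normal = .planeNormal(.xyz(ring)))
  })
  rows[!vapply(rows, is.null, logical(1))]
}

#' Detect Watson-Crick base pairs between two nucleic chains
#'
#' A pair is called when the purine N1 to pyrimidine N3 distance is at most
#' \code{nCutoff}, the base-plane normals agree within \code{planeCutoff}
#' degrees, and the C1'-C1' distance falls in \code{c1Range}. Modified
#' bases (5-methylcytosine, inosine, 1-aminopurine) pair through their
#' parent-base atoms. Pairs are returned in strand-I (first argument)
#' residue order.
#'
#' @param chainI,chainII atom data.frames of the two chains (strand I
#'   first). A \code{\link{Duplex}} built from the result uses the same
#'   order.
#' @param nCutoff purine-N1/pyrimidine-N3 distance cutoff (default 3.5).
#' @param planeCutoff maximum angle between base-plane normals, degrees
#'   (default 65).
#' @param c1Range allowed C1'-C1' distance range (default c(9, 11.5)).
#' @return data.frame with columns \code{resiI, resiJ, baseI, baseJ, type}.
#' @examples
#' d <- buildIdealBDNA("ACGTACGTACGT")
#' a <- atoms(d)
#' nrow(detectBasePairs(a[a$chain == "A", ], a[a$chain == "B", ]))
#' @export
detectBasePairs <- function(chainI, chainII, nCutoff = 3.5,
                            planeCutoff = 65, c1Range = c(9, 11.5)) {
  empty <- data.frame(resiI = integer(), resiJ = integer(),
                      baseI = character(), baseJ = character(),
                      type = character(), stringsAsFactors = FALSE)
  resI <- .residueTable(chainI)
  resII <- .residueTable(chainII)
  if (is.null(resI) || is.null(resII)) return(empty)
  if (length(resI) < 4 || length(resII) < 4)
    attr(empty, "short") <- TRUE
  cand <- list()
  for (i in seq_along(resI)) for (j in seq_along(resII)) {
    a <- resI[[i]]; b <- resII[[j]]
    if (a$purine == b$purine) next        # need one purine, one pyrimidine
    d <- .vnorm(a$wc - b$wc)
    if (d > nCutoff) next
    ang <- .deg(acos(.clamp(abs(sum(a$normal * b$normal)), 0, 1)))
    if (ang > planeCutoff) next
    c1c1 <- .vnorm(a$c1 - b$c1)
    if (c1c1 < c1Range[1] || c1c1 > c1Range[2]) next
    cand[[length(cand) + 1L]] <- list(i = i, j = j, d = d)
  }
  if (!length(cand)) return(empty)
  ## greedy one-to-one matching by donor-acceptor distance
  ord <- order(vapply(cand, `[[`, numeric(1), "d"))
  usedI <- integer(); usedJ <- integer()
  rows <- list()
  for (k in ord) {
    cc <- cand[[k]]
    if (cc$i %in% usedI || cc$j %in% usedJ) next
    usedI <- c(usedI, cc$i); usedJ <- c(usedJ, cc$j)
    a <- resI[[cc$i]]; b <- resII[[cc$j]]
    type <- if (identical(.wcPartner[[a$base]], b$base)) "WC"
      else if (all(sort(c(a$base, b$base)) %in% c("G", "T")) ||
               all(sort(c(a$base, b$base)) %in% c("G", "U"))) "wobble"
      else "noncanonical"
    rows[[length(rows) + 1L]] <- data.frame(
      resiI = a$resi, resiJ = b$resi, baseI = a$base, baseJ = b$base,
      type = type, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$resiI), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference frame of a single base pair
#'
#' The origin is the midpoint of the two C1' atoms; the y-axis runs along
#' C1'(I) to C1'(II); the z-axis is the mean base-plane normal; the x-axis
#' completes a right-handed triad and points towards the centroid of the
#' major-groove edge atoms (purine N7/O6/N6/C5, pyrimidine C5/N4/O4). The
#' minor-groove edge atoms (purine N3, pyrimidine O2) lie on the -x side.
#'
#' For a single pair the 5'->3' direction is unknown, so the z sign is
#' chosen to satisfy the major-groove rule; within a \code{\link{Duplex}}
#' the z axes follow the strand-I 5'->3' progression instead.
#'
#' @param resI,resII atom data.frames of the two paired residues (strand I
#'   residue first).
#' @return list with unit vectors \code{x, y, z} and \code{origin}.
#' @export
basePairFrame <- function(resI, resII) {
  f <- .pairFrameRaw(resI, resII)
  maj <- .grooveEdgeCentroid(resI, resII, "major")
  if (sum(f$x * (maj - f$origin)) < 0) {
    f$x <- -f$x; f$z <- -f$z
  }
  f
}

## frame with z sign as given by the raw mean normal (caller fixes sign)
.pairFrameRaw <- function(resI, resII) {
  need <- function(sub, nm, what) {
    row <- sub[sub$name == nm, , drop = FALSE]
    if (!nrow(row))
      stop("frame error: residue ", sub$resn[1], " ", sub$resi[1],
           " is missing atom ", nm, " (", what, ")")
    as.numeric(row[1, c("x", "y", "z")])
  }
  c1I <- need(resI, "C1'", "glycosidic")
  c1II <- need(resII, "C1'", "glycosidic")
  bI <- .baseLetter(resI$resn[1]); bII <- .baseLetter(resII$resn[1])
  ringI <- resI[resI$name %in%
                  (if (bI %in% .purineBases) .purineRing else .pyrimidineRing), ,
                drop = FALSE]
  ringII <- resII[resII$name %in%
                    (if (bII %in% .purineBases) .purineRing else .pyrimidineRing), ,
                  drop = FALSE]
  if (nrow(ringI) < 4 || nrow(ringII) < 4)
    stop("frame error: missing ring atoms for residue ",
         resI$resi[1], "/", resII$resi[1])
  nI <- .planeNormal(.xyz(ringI))
  nII <- .planeNormal(.xyz(ringII))
  if (sum(nI * nII) < 0) nII <- -nII
  zRaw <- .unit(nI + nII)
  origin <- (c1I + c1II) / 2
  y <- .unit(c1II - c1I)
  z <- .unit(zRaw - sum(zRaw * y) * y)
  x <- .cross3(y, z)
  list(origin = origin, x = x, y = y, z = z)
}

.grooveEdgeCentroid <- function(resI, resII, side = c("major", "minor")) {
  side <- match.arg(side)
  pick <- function(sub) {
    b <- .baseLetter(sub$resn[1])
    nm <- if (side == "major") {
      if (b %in% .purineBases) c("N7", "O6", "N6", "C5") else c("C5", "N4", "O4")
    } else {
      if (b %in% .purineBases) "N3" else "O2"
    }
    sub[sub$name %in% nm, c("x", "y", "z"), drop = FALSE]
  }
  m <- rbind(pick(resI), pick(resII))
  colMeans(as.matrix(m))
}

#' Build a Duplex from two chains
#'
#' Runs \code{\link{detectBasePairs}} and populates per-pair reference
#' frames (see \code{\link{basePairFrame}}); z axes are oriented along the
#' strand-I 5'->3' progression.
#'
#' @param chainI,chainII atom data.frames of strand I and strand II.
#' @param chainIdI,chainIdII chain identifiers recorded in the object.
#' @param source provenance list (free-form; carried into reports).
#' @param ... passed to \code{\link{detectBasePairs}}.
#' @return a \code{\link{Duplex}}, or \code{NULL} when fewer than 4 pairs
#'   are found.
#' @export
makeDuplex <- function(chainI, chainII, chainIdI = chainI$chain[1],
                       chainIdII = chainII$chain[1],
                       source = list(label = "asu"), ...) {
  pairs <- detectBasePairs(chainI, chainII, ...)
  if (nrow(pairs) < 4) return(NULL)
  n <- nrow(pairs)
  resOf <- function(sub, resi) sub[sub$resi == resi, , drop = FALSE]
  frames <- lapply(seq_len(n), function(i) {
    .pairFrameRaw(resOf(chainI, pairs$resiI[i]), resOf(chainII, pairs$resiJ[i]))
  })
  origins <- t(vapply(frames, `[[`, numeric(3), "origin"))
  ## orient z along the 5'->3' progression of strand I
  zs <- t(vapply(frames, `[[`, numeric(3), "z"))
  ys <- t(vapply(frames, `[[`, numeric(3), "y"))
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    tang <- origins[hi, ] - origins[lo, ]
    if (sum(zs[i, ] * tang) < 0) zs[i, ] <- -zs[i, ]
  }
  xs <- t(vapply(seq_len(n), function(i) .cross3(ys[i, ], zs[i, ]),
                 numeric(3)))
  ## sanity: x should face the major-groove edge
  majOK <- vapply(seq_len(n), function(i) {
    ctr <- .grooveEdgeCentroid(resOf(chainI, pairs$resiI[i]),
                               resOf(chainII, pairs$resiJ[i]), "major")
    sum(xs[i, ] * (ctr - origins[i, ])) > 0
  }, logical(1))
  if (mean(majOK) < 0.5) {
    ## mirror-image coordinates: the right-handed triad with z along 5'->3'
    ## points x at the minor groove. Groove identity is chemical, so flip x
    ## (and z, to keep the triad right-handed); sector labels stay correct
    ## and only the 5'->3' sign convention of z is sacrificed.
    xs <- -xs
    zs <- -zs
    warning("base-pair x-axes faced away from the major-groove edge ",
            "(mirror-image coordinates?); frames re-anchored chemically")
  }
  seqI <- paste(pairs$baseI, collapse = "")
  seqII <- paste(rev(pairs$baseJ), collapse = "")   # 5'->3' of strand II
  new("Duplex",
      atoms = rbind(chainI, chainII), pairs = pairs, origins = origins,
      xAxes = xs, yAxes = ys, zAxes = zs, sequenceI = seqI,
      sequenceII = seqII, chainI = as.character(chainIdI),
      chainII = as.character(chainIdII), source = source)
}

#' Duplexes present in a crystal model
#'
#' Pairs up the nucleic chains of the asymmetric unit into duplexes.
#'
#' @param model a \code{\link{CrystalModel}}.
#' @param ... passed to \code{\link{detectBasePairs}}.
#' @return list of \code{\link{Duplex}}.
#' @export
findDuplexes <- function(model, ...) {
  groups <- .groupNucleicChains(model)
  out <- list()
  for (g in groups) {
    if (length(g) != 2) next
    a <- model@atoms[model@atoms$chain == g[1], , drop = FALSE]
    b <- model@atoms[model@atoms$chain == g[2], , drop = FALSE]
    d <- makeDuplex(a, b, source = list(label = paste(g, collapse = "")), ...)
    if (!is.null(d)) out[[length(out) + 1L]] <- d
  }
  out
}

## rigid transform of a duplex (proper rotations only; frames move rigidly)
.transformDuplex <- function(duplex, rot, trans, source = duplex@source) {
  stopifnot(det(rot) > 0)
  d <- duplex
  d@atoms <- .transformAtoms(duplex@atoms, rot, trans)
  d@origins <- sweep(duplex@origins %*% t(rot), 2, trans, "+")
  d@xAxes <- duplex@xAxes %*% t(rot)
  d@yAxes <- duplex@yAxes %*% t(rot)
  d@zAxes <- duplex@zAxes %*% t(rot)
  d@source <- source
  d
}

#' Fit the best linear helical axis of a duplex
#'
#' Total-least-squares line through the base-pair origins: the first
#' principal direction of the centred origin cloud. The direction sign
#' follows increasing pair index (strand-I 5'->3'). The fit RMSD is the RMS
#' distance of the origins to the line; above \code{curvatureThreshold}
#' (default 2 Angstrom) the duplex is flagged as curved and downstream
#' crossovers are marked low-confidence.
#'
#' @param x a \code{\link{Duplex}}, or an n x 3 matrix of pair origins.
#' @param curvatureThreshold RMSD (Angstrom) above which
#'   \code{curvatureFlag} is set.
#' @param ... unused.
#' @return a \code{\link{HelicalAxisFit}}.
#' @examples
#' d <- buildIdealBDNA("ACGTACGTACGT")
#' fitLinearAxis(d)
#' @export
setMethod("fitLinearAxis", "Duplex", function(x, curvatureThreshold = 2, ...) {
  fitLinearAxis(x@origins, curvatureThreshold = curvatureThreshold)
})

#' @rdname fitLinearAxis-Duplex-method
#' @export
setMethod("fitLinearAxis", "matrix", function(x, curvatureThreshold = 2, ...) {
  if (nrow(x) < 2) stop("need at least 2 origins to fit an axis")
  ctr <- colMeans(x)
  centred <- sweep(x, 2, ctr)
  if (max(abs(centred)) < 1e-12)
    stop("degenerate origin cloud: all pair origins identical")
  s <- svd(centred)
  dir <- s$v[, 1]
  if (sum(dir * (x[nrow(x), ] - x[1, ])) < 0) dir <- -dir
  proj <- as.numeric(centred %*% dir)
  residVec <- centred - proj %*% t(dir)
  rmsd <- sqrt(mean(rowSums(residVec^2)))
  if (rmsd < 1e-9) rmsd <- 0   # collinear origins are exactly on the line
  new("HelicalAxisFit", point = ctr, direction = dir, rmsd = rmsd,
      curvatureFlag = rmsd > curvatureThreshold, extents = range(proj))
})

## split a long (e.g. nucleosomal) duplex into overlapping windows so that
## locally straight axes can be fitted; curvature_flag guards misuse
.splitDuplexWindows <- function(duplex, window = 12, step = 6) {
  n <- nrow(duplex@origins)
  if (n <= window + 4) return(list(duplex))
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    d <- duplex
    d@pairs <- duplex@pairs[idx, , drop = FALSE]
    d@origins <- duplex@origins[idx, , drop = FALSE]
    d@xAxes <- duplex@xAxes[idx, , drop = FALSE]
    d@yAxes <- duplex@yAxes[idx, , drop = FALSE]
    d@zAxes <- duplex@zAxes[idx, , drop = FALSE]
    d@sequenceI <- paste(d@pairs$baseI, collapse = "")
    d@sequenceII <- paste(rev(d@pairs$baseJ), collapse = "")
    keepRes <- (duplex@atoms$chain == duplex@chainI &
                  duplex@atoms$resi %in% d@pairs$resiI) |
      (duplex@atoms$chain == duplex@chainII &
         duplex@atoms$resi %in% d@pairs$resiJ)
    d@atoms <- duplex@atoms[keepRes, , drop = FALSE]
    d@source <- c(duplex@source, list(window = c(s, s + window - 1L)))
    d
  })
}
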