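#' @include crossover-analysis.R
NULL

#' Groove sector of a point relative to a duplex
#'
#' The nearest base-pair frame (by axial projection) is selected and the
#' in-plane angle theta between the point's offset (projected to the frame
#' xy-plane) and the +x (major-groove) direction is computed. Sectors
#' partition the circle: |theta| <= 60 is \code{major}, |theta| >= 120 is
#' \code{minor}, and everything between is \code{backbone_side}. The radial
#' distance is measured to the fitted helical axis.
#'
#' @param point numeric(3).
#' @param duplex a \code{\link{Duplex}}.
#' @param fit optional precomputed \code{\link{HelicalAxisFit}}.
#' @param rise axial overhang (Angstrom) beyond the terminal pair origins
#'   before a point is flagged out-of-range (default 3.4, one rise).
#' @return list with \code{sector}, \code{theta} (degrees), \code{radial}
#'   (Angstrom), \code{outOfRange}, and the nearest pair index \code{pair}.
#' @examples
#' d <- buildIdealBDNA("ACGTACGTACGT")
#' mid <- nPairs(d) %/% 2
#' p <- pairOrigins(d)[mid, ] + 8 * d@xAxes[mid, ]
#' grooveSector(p, d)$sector   # "major"
#' @export
grooveSector <- function(point, duplex, fit = NULL, rise = 3.4) {
  if (is.null(fit)) fit <- fitLinearAxis(duplex)
  dirp <- fit@direction
  proj <- sum((point - fit@point) * dirp)
  oproj <- as.numeric(sweep(duplex@origins, 2, fit@point) %*% dirp)
  outOfRange <- proj < min(oproj) - rise || proj > max(oproj) + rise
  k <- which.min(abs(oproj - proj))
  v <- point - duplex@origins[k, ]
  vx <- sum(v * duplex@xAxes[k, ])
  vy <- sum(v * duplex@yAxes[k, ])
  theta <- .deg(atan2(vy, vx))
  sector <- if (abs(theta) <= 60) "major"
    else if (abs(theta) >= 120) "minor"
    else "backbone_side"
  radialVec <- (point - fit@point) - proj * dirp
  list(sector = sector, theta = theta, radial = .vnorm(radialVec),
       outOfRange = outOfRange, pair = k)
}

## phosphorus atoms of a duplex, with residue bookkeeping
.phosphorusAtoms <- function(duplex) {
  duplex@atoms[duplex@atoms$name == "P", , drop = FALSE]
}

#' Classify the interaction mode of a crossover
#'
#' A phosphorus atom of one duplex "penetrates" the partner when its groove
#' sector is major (or minor) with a radial distance to the partner's axis
#' of at most \code{penetrationRadius}. At least one major-penetrating
#' phosphate gives MAJOR_GROOVE_BACKBONE; otherwise minor-penetrating gives
#' MINOR_GROOVE_BACKBONE (the self-fitted, "knob into hole" modes). With no
#' insertion, the groove of each duplex that faces the partner's closest
#' point decides between the juxtaposition modes MAJOR_MAJOR, MINOR_MINOR
#' and MAJOR_MINOR; when no facing groove is resolvable the crossover is
#' UNCLASSIFIED.
#'
#' @param crossover a \code{\link{Crossover}}.
#' @param penetrationRadius radial cutoff (Angstrom) for an inserted
#'   phosphate (default 10.5; the B-DNA phosphate radius is ~9-10).
#' @param insertionHalfWidth maximum in-plane angle (degrees) between an
#'   inserted phosphate and the groove axis (default 30). A genuinely
#'   inserted phosphate lies over the groove floor; phosphates of a closely
#'   apposed groove-groove partner graze the sector edges (in-plane angles
#'   beyond ~35 degrees) and must not count as insertions.
#' @return a \code{\link{ContactReport}} with mode and penetrating
#'   phosphates filled; anchors and bridges are added by
#'   \code{\link{detectAnchorContacts}} / \code{\link{detectCationBridges}}.
#' @export
classifyMode <- function(crossover, penetrationRadius = 10.5,
                         insertionHalfWidth = 30) {
  dup <- list(A = crossover@duplexA, B = crossover@duplexB)
  fit <- list(A = crossover@axisA, B = crossover@axisB)
  ## which face each duplex presents to the partner at the contact; the
  ## partner's origin centroid is a noise-stable stand-in for the contact
  ## direction (the closest point itself slides axially under coordinate
  ## noise for shallow crossings, landing on twist-misregistered frames)
  face <- list(
    A = grooveSector(colMeans(dup$B@origins), dup$A, fit = fit$A,
                     rise = Inf)$sector,
    B = grooveSector(colMeans(dup$A@origins), dup$B, fit = fit$B,
                     rise = Inf)$sector)
  pen <- list()
  for (side in c("A", "B")) {
    other <- if (side == "A") "B" else "A"
    pAtoms <- .phosphorusAtoms(dup[[side]])
    for (r in seq_len(nrow(pAtoms))) {
      p <- as.numeric(pAtoms[r, c("x", "y", "z")])
      gs <- grooveSector(p, dup[[other]], fit = fit[[other]])
      if (gs$outOfRange || gs$radial > penetrationRadius) next
      offFloor <- min(abs(gs$theta), abs(180 - abs(gs$theta)))
      if (offFloor > insertionHalfWidth) next
      if (gs$sector %in% c("major", "minor")) {
        pen[[length(pen) + 1L]] <- data.frame(
          donorDuplex = side, chain = pAtoms$chain[r], resi = pAtoms$resi[r],
          groove = gs$sector, radial = gs$radial, stringsAsFactors = FALSE)
      }
    }
  }
  pen <- if (length(pen)) do.call(rbind, pen) else
    data.frame(donorDuplex = character(), chain = character(),
               resi = integer(), groove = character(), radial = numeric(),
               stringsAsFactors = FALSE)
  if (any(pen$groove == "major")) {
    mode <- "MAJOR_GROOVE_BACKBONE"
    pen <- pen[pen$groove == "major", , drop = FALSE]
  } else if (any(pen$groove == "minor")) {
    mode <- "MINOR_GROOVE_BACKBONE"
  } else {
    faceA <- face$A
    faceB <- face$B
    mode <- if (faceA == "major" && faceB == "major") "MAJOR_MAJOR"
      else if (faceA == "minor" && faceB == "minor") "MINOR_MINOR"
      else if (all(sort(c(faceA, faceB)) == c("major", "minor"))) "MAJOR_MINOR"
      else "UNCLASSIFIED"
  }
  empty <- data.frame()
  new("ContactReport", crossover = crossover, mode = mode,
      penetratingPhosphates = pen, anchors = empty, bridges = empty)
}

.emptyAnchors <- function() {
  data.frame(kind = character(), donor = character(), base = character(),
             baseChain = character(), baseResi = integer(),
             phosChain = character(), phosResi = integer(),
             closestAtom = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect anchoring amino-group/phosphate contacts
#'
#' For each penetrating phosphate, amino-group donors of the penetrated
#' duplex (cytosine N4 for the major-groove modes, guanine N2 for the
#' minor-groove mode) are classified by their shortest distance to the
#' phosphate group: at most \code{hbondCutoff} is a hydrogen-bonded anchor;
#' within \code{proximalWindow} is a proximal anchor. Hydrogens are not
#' modelled, so all criteria are donor-heavy-atom to acceptor distances
#' (acceptors: the phosphate oxygens O1P/O2P/O5'/O3'). Groove-groove modes
#' carry no sequence-specific anchors and return an empty table. Each
#' anchor base is reported once, at its minimum distance.
#'
#' @param report a \code{\link{ContactReport}} from \code{\link{classifyMode}}.
#' @param hbondCutoff hydrogen-bond distance cutoff (default 3.4 Angstrom;
#'   chosen to abut the proximal window so the two classes are disjoint).
#' @param proximalWindow numeric(2), the proximal-anchor distance window
#'   (default c(3.5, 4.5)).
#' @return the report with the \code{anchors} table filled.
#' @export
detectAnchorContacts <- function(report, hbondCutoff = 3.4,
                                 proximalWindow = c(3.5, 4.5)) {
  gb <- report@mode %in% c("MAJOR_GROOVE_BACKBONE", "MINOR_GROOVE_BACKBONE")
  report@anchors <- .emptyAnchors()
  if (!gb || !nrow(report@penetratingPhosphates)) return(report)
  major <- report@mode == "MAJOR_GROOVE_BACKBONE"
  donorName <- if (major) "N4" else "N2"
  donorBase <- if (major) "C" else "G"
  cx <- report@crossover
  dup <- list(A = cx@duplexA, B = cx@duplexB)
  rows <- list()
  for (r in seq_len(nrow(report@penetratingPhosphates))) {
    ph <- report@penetratingPhosphates[r, ]
    target <- dup[[if (ph$donorDuplex == "A") "B" else "A"]]
    donorDup <- dup[[ph$donorDuplex]]
    phosRes <- donorDup@atoms[donorDup@atoms$chain == ph$chain &
                                donorDup@atoms$resi == ph$resi, , drop = FALSE]
    acc <- phosRes[phosRes$name %in% c("O1P", "O2P", "O5'", "O3'"), ,
                   drop = FALSE]
    if (!nrow(acc)) next
    base <- .baseLetter(target@atoms$resn)
    don <- target@atoms[!is.na(base) & base == donorBase &
                          target@atoms$name == donorName, , drop = FALSE]
    for (q in seq_len(nrow(don))) {
      dvec <- .distToPoint(.xyz(acc), as.numeric(don[q, c("x", "y", "z")]))
      dmin <- min(dvec)
      kind <- if (dmin <= hbondCutoff) {
        if (major) "hbond_anchor" else "guanine_minor_anchor"
      } else if (dmin >= proximalWindow[1] && dmin <= proximalWindow[2]) {
        "proximal_anchor"
      } else next
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, donor = donorName, base = donorBase,
        baseChain = don$chain[q], baseResi = don$resi[q],
        phosChain = ph$chain, phosResi = ph$resi,
        closestAtom = acc$name[which.min(dvec)], distance = dmin,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    ## one row per donor base, at its minimum distance
    key <- paste(tab$baseChain, tab$baseResi)
    tab <- tab[order(tab$distance), , drop = FALSE]
    tab <- tab[!duplicated(key[order(tab$distance)]), , drop = FALSE]
    tab <- tab[order(tab$baseChain, tab$baseResi), , drop = FALSE]
    rownames(tab) <- NULL
    report@anchors <- tab
  }
  report
}

.emptyBridges <- function() {
  data.frame(element = character(), chain = character(), resi = integer(),
             divalent = logical(), distA = numeric(), distB = numeric(),
             maxContact = numeric(), stringsAsFactors = FALSE)
}

#' Detect cation bridges between the two duplexes of a crossover
#'
#' An ion bridges when it contacts at least one DNA atom of each duplex
#' within \code{cutoff} (default 4.0 Angstrom, covering inner-sphere and
#' tight water-mediated geometries with unmodelled waters). Monovalent ions
#' are reported too, flagged non-divalent.
#'
#' @param report a \code{\link{ContactReport}}.
#' @param ions atom data.frame of cation sites (from \code{\link{ions}}),
#'   with a logical \code{divalent} column.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return the report with the \code{bridges} table filled.
#' @export
detectCationBridges <- function(report, ions, cutoff = 4.0) {
  report@bridges <- .emptyBridges()
  if (is.null(ions) || !nrow(ions)) return(report)
  cx <- report@crossover
  xyzA <- .xyz(cx@duplexA@atoms)
  xyzB <- .xyz(cx@duplexB@atoms)
  rows <- list()
  for (r in seq_len(nrow(ions))) {
    p <- as.numeric(ions[r, c("x", "y", "z")])
    dA <- min(.distToPoint(xyzA, p))
    dB <- min(.distToPoint(xyzB, p))
    if (dA <= cutoff && dB <= cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        element = ions$element[r], chain = ions$chain[r],
        resi = ions$resi[r],
        divalent = isTRUE(ions$divalent[r]),
        distA = dA, distB = dB, maxContact = max(dA, dB),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) report@bridges <- do.call(rbind, rows)
  report
}
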