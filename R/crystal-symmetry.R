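#' @include structure-io.R
NULL

#' Fractional-to-orthogonal transformation matrix
#'
#' Standard crystallographic orthogonalization convention: cell axis a lies
#' along x and b lies in the xy-plane. The determinant of the matrix equals
#' the unit-cell volume.
#'
#' @param cell a \code{\link{UnitCell}}.
#' @return 3x3 numeric matrix mapping fractional to orthogonal (Angstrom)
#'   coordinates.
#' @examples
#' orthogonalizationMatrix(UnitCell(10, 10, 10))
#' @export
orthogonalizationMatrix <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  ca <- cos(.rad(cell@alpha)); cb <- cos(.rad(cell@beta))
  cg <- cos(.rad(cell@gamma)); sg <- sin(.rad(cell@gamma))
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (!is.finite(v2) || v2 <= 0) stop("degenerate cell: non-positive volume")
  v <- sqrt(v2)
  matrix(c(
    cell@a, cell@b * cg, cell@c * cb,
    0,      cell@b * sg, cell@c * (ca - cb * cg) / sg,
    0,      0,           cell@c * v / sg), 3, 3, byrow = TRUE)
}

## partition the nucleic chains of a model into duplex-candidate groups:
## chain pairs that form >= 4 Watson-Crick pairs travel together through
## symmetry expansion, so duplex identity survives the transformation
.groupNucleicChains <- function(model, minPairs = 4) {
  ch <- model@nucleicChains
  if (!length(ch)) return(list())
  if (length(ch) == 1) return(list(ch))
  nuc <- model@atoms[model@atoms$chain %in% ch, , drop = FALSE]
  groups <- list()
  used <- character()
  for (i in seq_along(ch)) {
    if (ch[i] %in% used) next
    partner <- NULL
    bestN <- minPairs - 1L
    for (j in seq_along(ch)) {
      if (i == j || ch[j] %in% used) next
      bp <- detectBasePairs(nuc[nuc$chain == ch[i], , drop = FALSE],
                            nuc[nuc$chain == ch[j], , drop = FALSE])
      if (nrow(bp) > bestN) { bestN <- nrow(bp); partner <- ch[j] }
    }
    if (!is.null(partner)) {
      groups[[length(groups) + 1L]] <- c(ch[i], partner)
      used <- c(used, ch[i], partner)
    } else {
      groups[[length(groups) + 1L]] <- ch[i]
      used <- c(used, ch[i])
    }
  }
  groups
}

#' Expand crystal packing neighbours of the nucleic chains
#'
#' Generates every distinct symmetry image (space-group operator plus
#' lattice translation) of each nucleic chain group that has at least one
#' atom within \code{radius} of any asymmetric-unit atom. The identity
#' zero-shift copy of each group is always included and flagged. Duplicate
#' transforms (agreeing to 1e-6) are removed.
#'
#' @param model a \code{\link{CrystalModel}} with cell and operators.
#' @param radius contact radius in Angstrom (default 25: inter-axial duplex
#'   separations of interest are below ~22, plus margin).
#' @param groups optional list of chain-id vectors; defaults to automatic
#'   duplex-candidate grouping of the nucleic chains.
#' @return list of \code{\link{PlacedCopy}}.
#' @examples
#' d <- buildIdealBDNA("ACGTACGTACGT")
#' f <- tempfile(fileext = ".pdb")
#' makeMockCrystal(atoms(d), UnitCell(100, 100, 100), path = f)
#' copies <- expandNeighborhood(readStructure(f), radius = 20)
#' length(copies)  # isolated molecule: identity only
#' @export
expandNeighborhood <- function(model, radius = 25, groups = NULL) {
  stopifnot(is(model, "CrystalModel"), radius > 0)
  if (is.null(model@cell))
    stop("model has no unit cell; cannot expand symmetry")
  if (!length(model@operators))
    stop("operators unavailable: model carries no symmetry operators")
  if (is.null(groups)) groups <- .groupNucleicChains(model)
  if (!length(groups)) return(list())
  M <- orthogonalizationMatrix(model@cell)
  Minv <- solve(M)
  refXyz <- .xyz(model@atoms)
  ## lattice-shift search bound: enough cells to cover radius + model extent
  ## along each cell height (cell height_i = 1 / |row i of Minv|)
  diam <- .vnorm(apply(refXyz, 2, max) - apply(refXyz, 2, min))
  heights <- 1 / sqrt(rowSums(Minv^2))
  nmax <- pmin(ceiling((radius + diam) / heights) + 1L, 6L)
  shifts <- as.matrix(expand.grid(u = -nmax[1]:nmax[1],
                                  v = -nmax[2]:nmax[2],
                                  w = -nmax[3]:nmax[3]))
  refCtr <- colMeans(refXyz)
  out <- list()
  seen <- character()
  for (g in groups) {
    gAtoms <- model@atoms[model@atoms$chain %in% g, , drop = FALSE]
    gXyz <- .xyz(gAtoms)
    gCtr <- colMeans(gXyz)
    for (op in model@operators) {
      rotOrth <- M %*% op@rot %*% Minv
      base <- gXyz %*% t(rotOrth)
      tOp <- as.numeric(M %*% op@trans)
      ctrRot <- as.numeric(rotOrth %*% gCtr)
      for (k in seq_len(nrow(shifts))) {
        s <- as.integer(shifts[k, ])
        trans <- tOp + as.numeric(M %*% s)
        isIdent <- max(abs(rotOrth - diag(3))) < 1e-9 && .vnorm(trans) < 1e-9
        if (!isIdent && .vnorm(ctrRot + trans - refCtr) - diam > radius) next
        moved <- sweep(base, 2, trans, "+")
        if (!isIdent) {
          if (.minCrossDist(moved, refXyz) > radius) next
        }
        key <- paste(c(round(rotOrth, 6), round(trans, 6)), collapse = ",")
        key <- paste(paste(sort(g), collapse = "+"), key)
        if (key %in% seen) next
        seen <- c(seen, key)
        newAtoms <- gAtoms
        newAtoms$x <- moved[, 1]; newAtoms$y <- moved[, 2]
        newAtoms$z <- moved[, 3]
        out[[length(out) + 1L]] <- new("PlacedCopy",
          chainIds = g, operator = op, shift = s, rot = rotOrth,
          trans = trans, atoms = newAtoms, isIdentity = isIdent)
      }
    }
  }
  out
}
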