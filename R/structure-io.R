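#' @include spacegroups.R
NULL

## ---- chemical dictionaries ----

## residue-name -> one-letter base code; I = inosine (pairs like G with C)
.baseMap <- c(
  DA = "A", A = "A", ADE = "A",
  DC = "C", C = "C", CYT = "C",
  DG = "G", G = "G", GUA = "G",
  DT = "T", T = "T", THY = "T",
  DU = "U", U = "U", URA = "U",
  "5CM" = "C", "5MC" = "C", MCY = "C",   # 5-methylcytosine
  DI = "I", I = "I", INO = "I",          # inosine
  "1AP" = "A", AP7 = "A"                 # 1-aminopurine -> parent purine
)

.purineBases <- c("A", "G", "I")

.divalentIons <- c("MG", "CA", "MN", "ZN", "SR", "BA", "CD", "NI", "CU", "CO")
.monovalentIons <- c("NA", "K", "LI", "RB", "CS", "TL")
.waterResn <- c("HOH", "WAT", "DOD", "H2O")

.baseLetter <- function(resn) {
  out <- .baseMap[toupper(trimws(resn))]
  unname(out)
}

## normalise atom names across PDB dialects: * -> ', OP1/OP2 -> O1P/O2P,
## thymine methyl C5M -> C7
.normalizeAtomName <- function(name) {
  name <- gsub("\\*", "'", trimws(name))
  swap <- c(OP1 = "O1P", OP2 = "O2P", OP3 = "O3P", C5M = "C7")
  hit <- match(name, names(swap))
  name[!is.na(hit)] <- swap[hit[!is.na(hit)]]
  name
}

## infer element symbols from atom names when the element column is absent
.inferElement <- function(name, resn) {
  el <- character(length(name))
  resnU <- toupper(trimws(resn))
  nameU <- toupper(trimws(name))
  ionHit <- resnU %in% c(.divalentIons, .monovalentIons) & nameU == resnU
  el[ionHit] <- resnU[ionHit]
  rest <- !ionHit
  core <- gsub("[0-9']", "", nameU[rest])
  el[rest] <- substr(core, 1, 1)
  ## capitalisation: "MG" -> "Mg"
  paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
}

.emptyAtoms <- function() {
  data.frame(record = character(), serial = integer(), name = character(),
             altloc = character(), resn = character(), chain = character(),
             resi = integer(), icode = character(), x = numeric(),
             y = numeric(), z = numeric(), occ = numeric(),
             element = character(), stringsAsFactors = FALSE)
}

## ---- constructors ----

#' Construct a UnitCell
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param spaceGroup Hermann-Mauguin symbol.
#' @return a \code{\link{UnitCell}} object.
#' @examples
#' UnitCell(25, 25, 25, spaceGroup = "P 1")
#' @export
UnitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                     spaceGroup = "P 1") {
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma, spaceGroup = spaceGroup)
}

## resolve alternate locations: keep highest occupancy, ties -> first in file
.resolveAltloc <- function(atoms) {
  if (!nrow(atoms)) return(atoms)
  key <- paste(atoms$chain, atoms$resi, atoms$icode, atoms$name, sep = "|")
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  keep <- ord[!duplicated(key[ord])]
  out <- atoms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.findIons <- function(atoms) {
  if (!nrow(atoms)) {
    out <- .emptyAtoms(); out$divalent <- logical(); return(out)
  }
  elU <- toupper(atoms$element)
  resnU <- toupper(trimws(atoms$resn))
  metal <- elU %in% c(.divalentIons, .monovalentIons)
  ## a metal atom counts as a cation site when its residue is the bare ion
  ## (resn equals the element) or a metal complex such as cobalt hexammine
  bare <- metal & (resnU == elU | resnU %in% c("NCO", "NC3"))
  out <- atoms[bare & !(resnU %in% .waterResn), , drop = FALSE]
  out$divalent <- toupper(out$element) %in% .divalentIons |
    toupper(trimws(out$resn)) %in% c("NCO", "NC3")  # Co(NH3)6(3+)
  rownames(out) <- NULL
  out
}

.findNucleicChains <- function(atoms) {
  if (!nrow(atoms)) return(character())
  base <- .baseLetter(atoms$resn)
  nuc <- !is.na(base)
  hasC1 <- atoms$name == "C1'"
  chains <- sort(unique(atoms$chain[nuc & hasC1]))
  chains
}

#' Assemble a CrystalModel from an atom table
#'
#' Classifies nucleic chains and cation sites and attaches cell/symmetry
#' metadata. Normally called by \code{\link{readStructure}}, but exported so
#' synthetic structures can be assembled in code.
#'
#' @param atoms atom data.frame (see \code{\link{CrystalModel}}).
#' @param cell a \code{UnitCell} or \code{NULL}.
#' @param operators list of \code{SymmetryOperator}; when empty and a cell
#'   with a known space group is present, looked up from the internal table.
#' @return a \code{\link{CrystalModel}}.
#' @export
makeCrystalModel <- function(atoms, cell = NULL, operators = list()) {
  atoms <- .resolveAltloc(atoms)
  if (!length(operators) && !is.null(cell)) {
    operators <- spaceGroupOperators(cell@spaceGroup)
  }
  new("CrystalModel", atoms = atoms, cell = cell, operators = operators,
      nucleicChains = .findNucleicChains(atoms), ions = .findIons(atoms))
}

## ---- PDB reading ----

.readPDB <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## first model only
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 1) {
    mend <- grep("^ENDMDL", lines)
    lines <- c(lines[seq_len(mstart[1])],
               lines[(mstart[1] + 1):(mend[1] - 1)])
  }
  cell <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    cr <- cr[1]
    num <- function(a, b) suppressWarnings(as.numeric(substr(cr, a, b)))
    sg <- trimws(substr(cr, 56, 66))
    vals <- c(num(7, 15), num(16, 24), num(25, 33),
              num(34, 40), num(41, 47), num(48, 54))
    if (all(is.finite(vals)) && all(vals[1:3] > 0)) {
      cell <- UnitCell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6],
                       spaceGroup = if (nzchar(sg)) sg else "P 1")
    }
  }
  ## symmetry operator strings from the REMARK 290 table, when present
  ops <- list()
  symLines <- grep("^REMARK 290 {3,}[0-9]{4,6} {2,}", lines, value = TRUE)
  if (length(symLines)) {
    labs <- trimws(sub("^REMARK 290 +[0-9]+ +", "", symLines))
    labs <- labs[grepl("^[-+XYZxyz0-9/, ]+$", labs) & grepl(",", labs)]
    ops <- lapply(labs, parseSymop)
  }
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (!length(sel))
    stop("format error: no ATOM/HETATM records found in ", path)
  rec <- lines[sel]
  numcol <- function(a, b) suppressWarnings(as.numeric(substr(rec, a, b)))
  x <- numcol(31, 38); y <- numcol(39, 46); z <- numcol(47, 54)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("format error: unparseable coordinates at line ", sel[bad[1]],
         " of ", path)
  occ <- numcol(55, 60)
  occ[!is.finite(occ)] <- 1
  element <- trimws(substr(rec, 77, 78))
  name <- .normalizeAtomName(substr(rec, 13, 16))
  resn <- trimws(substr(rec, 18, 20))
  miss <- !nzchar(element)
  if (any(miss)) element[miss] <- .inferElement(name[miss], resn[miss])
  ## normalise capitalisation ("MG " in old files)
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  atoms <- data.frame(
    record = trimws(substr(rec, 1, 6)),
    serial = suppressWarnings(as.integer(substr(rec, 7, 11))),
    name = name,
    altloc = trimws(substr(rec, 17, 17)),
    resn = resn,
    chain = trimws(substr(rec, 22, 22)),
    resi = suppressWarnings(as.integer(substr(rec, 23, 26))),
    icode = trimws(substr(rec, 27, 27)),
    x = x, y = y, z = z, occ = occ, element = element,
    stringsAsFactors = FALSE)
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  list(atoms = atoms, cell = cell, operators = ops)
}

## ---- minimal mmCIF reading ----

.cifTokens <- function(line) {
  out <- character(); i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L)); i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[[:space:]]", substr(line, j, j))) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L)); i <- j
    }
  }
  out
}

.readmmCIF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  ## single-value items
  kv <- list()
  for (ln in grep("^_", lines, value = TRUE)) {
    toks <- .cifTokens(ln)
    if (length(toks) >= 2) kv[[tolower(toks[1])]] <- toks[2]
  }
  getnum <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) return(NA_real_)
    suppressWarnings(as.numeric(gsub("\\(.*\\)", "", v)))
  }
  cell <- NULL
  a <- getnum("_cell.length_a")
  if (is.finite(a)) {
    sg <- kv[["_symmetry.space_group_name_h-m"]]
    if (is.null(sg)) sg <- kv[["_space_group.name_h-m_alt"]]
    if (is.null(sg)) sg <- "P 1"
    cell <- UnitCell(a, getnum("_cell.length_b"), getnum("_cell.length_c"),
                     getnum("_cell.angle_alpha"), getnum("_cell.angle_beta"),
                     getnum("_cell.angle_gamma"), spaceGroup = sg)
  }
  ## loops
  loops <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "loop_") {
      hdr <- character(); j <- i + 1L
      while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
        hdr <- c(hdr, tolower(.cifTokens(lines[j])[1])); j <- j + 1L
      }
      vals <- character()
      while (j <= length(lines)) {
        t <- trimws(lines[j])
        if (t == "" || t == "loop_" || grepl("^(_|data_)", t)) break
        vals <- c(vals, .cifTokens(lines[j])); j <- j + 1L
      }
      if (length(hdr) && length(vals) %% length(hdr) == 0) {
        m <- matrix(vals, ncol = length(hdr), byrow = TRUE)
        colnames(m) <- hdr
        loops[[length(loops) + 1L]] <- m
      }
      i <- j
    } else i <- i + 1L
  }
  ops <- list()
  for (lp in loops) {
    oc <- intersect(c("_symmetry_equiv.pos_as_xyz",
                      "_space_group_symop.operation_xyz"), colnames(lp))
    if (length(oc)) ops <- lapply(lp[, oc[1]], parseSymop)
  }
  at <- NULL
  for (lp in loops) if (any(grepl("^_atom_site\\.", colnames(lp)))) at <- lp
  if (is.null(at)) stop("format error: no _atom_site loop in ", path)
  pick <- function(...) {
    for (k in c(...)) if (k %in% colnames(at)) return(at[, k])
    rep(NA_character_, nrow(at))
  }
  modelnum <- pick("_atom_site.pdbx_pdb_model_num")
  keep <- if (all(is.na(modelnum))) rep(TRUE, nrow(at)) else
    modelnum == modelnum[1]
  clean <- function(v) { v[v %in% c(".", "?")] <- ""; v }
  name <- .normalizeAtomName(clean(pick("_atom_site.auth_atom_id",
                                        "_atom_site.label_atom_id"))[keep])
  resn <- clean(pick("_atom_site.auth_comp_id",
                     "_atom_site.label_comp_id"))[keep]
  element <- clean(pick("_atom_site.type_symbol"))[keep]
  miss <- !nzchar(element)
  if (any(miss)) element[miss] <- .inferElement(name[miss], resn[miss])
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  occ <- suppressWarnings(as.numeric(pick("_atom_site.occupancy")[keep]))
  occ[!is.finite(occ)] <- 1
  atoms <- data.frame(
    record = clean(pick("_atom_site.group_pdb"))[keep],
    serial = suppressWarnings(as.integer(pick("_atom_site.id")[keep])),
    name = name,
    altloc = clean(pick("_atom_site.label_alt_id"))[keep],
    resn = resn,
    chain = clean(pick("_atom_site.auth_asym_id",
                       "_atom_site.label_asym_id"))[keep],
    resi = suppressWarnings(as.integer(pick("_atom_site.auth_seq_id",
                                            "_atom_site.label_seq_id")[keep])),
    icode = clean(pick("_atom_site.pdbx_pdb_ins_code"))[keep],
    x = suppressWarnings(as.numeric(pick("_atom_site.cartn_x")[keep])),
    y = suppressWarnings(as.numeric(pick("_atom_site.cartn_y")[keep])),
    z = suppressWarnings(as.numeric(pick("_atom_site.cartn_z")[keep])),
    occ = occ, element = element, stringsAsFactors = FALSE)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("format error: non-numeric coordinates in _atom_site of ", path)
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  list(atoms = atoms, cell = cell, operators = ops)
}

## ---- public API ----

#' Read a macromolecular structure file
#'
#' Parses a PDB or mmCIF coordinate file into a \code{\link{CrystalModel}}:
#' all ATOM/HETATM records of the first model, the unit cell and space group
#' when a crystal record is present, symmetry operators (from the file when
#' given, otherwise from the internal space-group table), with alternate
#' locations resolved to the highest-occupancy conformer (ties keep the
#' first encountered) and monoatomic cations separated from drugs and
#' waters.
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @return a \code{\link{CrystalModel}}.
#' @examples
#' d <- buildIdealBDNA("ACGTACGTACGT")
#' f <- tempfile(fileext = ".pdb")
#' makeMockCrystal(atoms(d), UnitCell(100, 100, 100), path = f)
#' m <- readStructure(f)
#' nucleicChains(m)
#' @export
readStructure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- if (dialect == "pdb") .readPDB(path) else .readmmCIF(path)
  makeCrystalModel(parsed$atoms, cell = parsed$cell,
                   operators = parsed$operators)
}

#' Write a CrystalModel as a PDB file
#'
#' Emits standard PDB with a CRYST1 record. A model without a cell is
#' written as P 1 with a dummy 1 Angstrom cell (with a warning). Reading
#' the result back preserves atom count, names and positions to 1e-3
#' Angstrom (the PDB coordinate precision).
#'
#' @param model a \code{\link{CrystalModel}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(model, path) {
  cell <- model@cell
  if (is.null(cell)) {
    warning("model has no unit cell; writing dummy 1 A P 1 cell")
    cell <- UnitCell(1, 1, 1)
  }
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cell@a, cell@b, cell@c, cell@alpha, cell@beta, cell@gamma,
                   cell@spaceGroup, max(1L, length(model@operators)))
  at <- model@atoms
  fmtName <- function(nm, el) {
    ## element-aligned atom-name field (cols 13-16)
    ifelse(nchar(nm) >= 4 | nchar(el) > 1,
           sprintf("%-4s", substr(nm, 1, 4)), sprintf(" %-3s", nm))
  }
  if (nrow(at)) {
    rec <- ifelse(at$record == "HETATM", "HETATM", "ATOM  ")
    body <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, at$serial %% 100000L, fmtName(at$name, at$element),
                    substr(at$altloc, 1, 1), at$resn, substr(at$chain, 1, 1),
                    at$resi %% 10000L, substr(at$icode, 1, 1),
                    at$x, at$y, at$z, at$occ, 0,
                    toupper(at$element))
    ## TER after each chain's last ATOM record
    out <- character()
    prev <- NULL
    for (i in seq_along(body)) {
      if (!is.null(prev) && at$chain[i] != prev && rec[i - 1] == "ATOM  ")
        out <- c(out, "TER")
      out <- c(out, body[i])
      prev <- at$chain[i]
    }
    lines <- c(lines, out)
  }
  lines <- c(lines, "END")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write PDB to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
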