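#' @include synthetic-data.R
NULL

.modePretty <- c(
  MAJOR_GROOVE_BACKBONE = "Major-groove/backbone",
  MINOR_GROOVE_BACKBONE = "Minor-groove/backbone",
  MAJOR_MAJOR = "Major <> Major",
  MINOR_MINOR = "Minor <> Minor",
  MAJOR_MINOR = "Major <> Minor",
  UNCLASSIFIED = "Unclassified")

#' Analysis configuration
#'
#' Bundles every geometric threshold of the pipeline, so that a run is
#' fully determined by (file, config). All distances are in Angstrom.
#'
#' @param contactRadius symmetry-expansion contact radius (default 25).
#' @param maxInteraxial maximum interaxial distance for a crossover
#'   (default 22).
#' @param penetrationRadius radial cutoff for an inserted phosphate
#'   (default 10.5).
#' @param insertionHalfWidth in-plane groove-floor half-width for an
#'   inserted phosphate, degrees (default 30).
#' @param hbondCutoff anchor hydrogen-bond cutoff (default 3.4).
#' @param proximalWindow proximal-anchor window (default c(3.5, 4.5)).
#' @param bridgeCutoff cation-bridge contact cutoff (default 4.0).
#' @param curvatureRmsd axis-fit RMSD above which a duplex counts as curved
#'   (default 2.0).
#' @param windowSize base pairs per axis window for long (bent) duplexes
#'   (default 12).
#' @param minOverlap interior margin for crossover closest points
#'   (default 3.4, one rise).
#' @param outputFormat "tsv" or "json".
#' @return a list of class \code{RunConfig}.
#' @examples
#' cfg <- runConfig(contactRadius = 20)
#' @export
runConfig <- function(contactRadius = 25, maxInteraxial = 22,
                      penetrationRadius = 10.5, insertionHalfWidth = 30,
                      hbondCutoff = 3.4,
                      proximalWindow = c(3.5, 4.5), bridgeCutoff = 4.0,
                      curvatureRmsd = 2.0, windowSize = 12,
                      minOverlap = 3.4, outputFormat = c("tsv", "json")) {
  outputFormat <- match.arg(outputFormat)
  cfg <- list(contactRadius = contactRadius, maxInteraxial = maxInteraxial,
              penetrationRadius = penetrationRadius,
              insertionHalfWidth = insertionHalfWidth,
              hbondCutoff = hbondCutoff, proximalWindow = proximalWindow,
              bridgeCutoff = bridgeCutoff, curvatureRmsd = curvatureRmsd,
              windowSize = windowSize, minOverlap = minOverlap,
              outputFormat = outputFormat)
  nums <- unlist(cfg[names(cfg) != "outputFormat"])
  if (any(!is.finite(nums)) || any(nums <= 0))
    stop("all RunConfig cutoffs must be positive numbers")
  if (proximalWindow[1] >= proximalWindow[2])
    stop("proximalWindow must be increasing")
  structure(cfg, class = "RunConfig")
}

#' Write / read a RunConfig as a flat key=value file
#' @param config a \code{RunConfig}.
#' @param path file path.
#' @return \code{readRunConfig} returns a \code{RunConfig};
#'   \code{writeRunConfig} its \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, "=", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  kv <- strsplit(readLines(path), "=")
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (all(is.finite(num))) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(runConfig, vals)
}

## pool the asymmetric-unit ions through the placed-copy transforms
.expandIons <- function(model, copies) {
  base <- model@ions
  if (!nrow(base)) return(base)
  seen <- character()
  rows <- list()
  transforms <- c(list(list(rot = diag(3), trans = c(0, 0, 0))),
                  lapply(copies, function(cp) list(rot = cp@rot,
                                                   trans = cp@trans)))
  for (tr in transforms) {
    moved <- .transformAtoms(base, tr$rot, tr$trans)
    for (r in seq_len(nrow(moved))) {
      key <- paste(round(moved$x[r], 3), round(moved$y[r], 3),
                   round(moved$z[r], 3))
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- moved[r, , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## markup: hydrogen-bonded anchors as [C], proximal anchors as (C), on the
## strand-I sequence of the penetrated duplex (plain-text stand-ins for the
## bold / bold-italic typography of printed tables)
.markupSequence <- function(report) {
  cx <- report@crossover
  if (!nrow(report@anchors)) {
    dup <- cx@duplexA
    return(dup@sequenceI)
  }
  donor <- report@penetratingPhosphates$donorDuplex[1]
  dup <- if (donor == "A") cx@duplexB else cx@duplexA
  letters1 <- strsplit(dup@sequenceI, "")[[1]]
  marks <- rep("", length(letters1))
  for (r in seq_len(nrow(report@anchors))) {
    a <- report@anchors[r, ]
    pos <- if (a$baseChain == dup@chainI)
      match(a$baseResi, dup@pairs$resiI) else match(a$baseResi, dup@pairs$resiJ)
    if (is.na(pos)) next
    m <- if (a$kind %in% c("hbond_anchor", "guanine_minor_anchor")) "[" else "("
    ## hydrogen bonds take precedence over proximal marks at one position
    if (marks[pos] != "[") marks[pos] <- m
  }
  paste(vapply(seq_along(letters1), function(i) {
    switch(marks[i],
           "[" = paste0("[", letters1[i], "]"),
           "(" = paste0("(", letters1[i], ")"),
           letters1[i])
  }, character(1)), collapse = "")
}

.cationLabel <- function(bridges) {
  if (!nrow(bridges)) return("")
  lab <- ifelse(bridges$divalent, paste0(bridges$element, "2+"),
                paste0(bridges$element, "+"))
  paste(sort(unique(lab)), collapse = ",")
}

#' Analyse the crossovers of one crystal structure
#'
#' Runs the full pipeline: read, symmetry expansion, duplex detection, axis
#' fitting, crossover search, interaction-mode classification, anchor and
#' cation-bridge detection. Deterministic given (input, config). Long bent
#' duplexes (nucleosomal DNA) are analysed in overlapping axis windows of
#' \code{config$windowSize} pairs.
#'
#' @param x path to a PDB/mmCIF file, or a \code{\link{CrystalModel}}.
#' @param config a \code{\link{runConfig}}.
#' @param entryId identifier used in the report rows (defaults to the file
#'   base name).
#' @param expand expand crystal symmetry (default TRUE when cell and
#'   operators are available).
#' @return list of class \code{CrossoverAnalysis} with elements
#'   \code{table} (one row per crossover: mode, space_group, sequence with
#'   anchor markup, cation, crossing_angle_deg, entry_id, plus exact alpha,
#'   distance, provenance and confidence), \code{reports} (the
#'   \code{\link{ContactReport}} objects) and \code{model}.
#' @examples
#' cr <- buildCrossover(60, 18, mode = "groove_backbone_major")
#' f <- tempfile(fileext = ".pdb")
#' makeMockCrystal(list(cr$duplexA, cr$duplexB), UnitCell(120, 120, 120),
#'                 path = f)
#' res <- analyzeStructure(f)
#' res$table[, c("mode", "crossing_angle_deg")]
#' @export
analyzeStructure <- function(x, config = runConfig(), entryId = NULL,
                             expand = TRUE) {
  model <- if (is(x, "CrystalModel")) x else
    tryCatch(readStructure(x),
             error = function(e) stop("stage structure_io: ",
                                      conditionMessage(e), call. = FALSE))
  if (is.null(entryId))
    entryId <- if (is.character(x)) sub("\\.[^.]+$", "", basename(x)) else "model"
  doExpand <- expand && !is.null(model@cell) && length(model@operators) > 0
  copies <- if (doExpand) {
    tryCatch(expandNeighborhood(model, radius = config$contactRadius),
             error = function(e) stop("stage crystal_symmetry: ",
                                      conditionMessage(e), call. = FALSE))
  } else list()
  ## duplexes of the asymmetric unit ...
  groups <- .groupNucleicChains(model)
  auDuplex <- list()
  for (g in groups) {
    if (length(g) != 2) next
    nuc <- model@atoms[!is.na(.baseLetter(model@atoms$resn)), , drop = FALSE]
    d <- makeDuplex(nuc[nuc$chain == g[1], , drop = FALSE],
                    nuc[nuc$chain == g[2], , drop = FALSE],
                    source = list(label = paste(sort(g), collapse = "")))
    if (!is.null(d)) auDuplex[[paste(sort(g), collapse = "+")]] <- d
  }
  if (!length(auDuplex))
    return(.emptyAnalysis(model, entryId))
  ## ... carried through every placed copy
  units <- list()
  if (length(copies)) {
    for (cp in copies) {
      key <- paste(sort(cp@chainIds), collapse = "+")
      src <- auDuplex[[key]]
      if (is.null(src)) next
      dup <- if (det(cp@rot) > 0) {
        .transformDuplex(src, cp@rot, cp@trans,
                         source = list(label = src@source$label,
                                       operator = cp@operator@label,
                                       shift = cp@shift))
      } else {
        at <- cp@atoms
        makeDuplex(at[at$chain == src@chainI, , drop = FALSE],
                   at[at$chain == src@chainII, , drop = FALSE],
                   source = list(label = src@source$label,
                                 operator = cp@operator@label,
                                 shift = cp@shift))
      }
      if (!is.null(dup)) units[[length(units) + 1L]] <- dup
    }
  } else {
    units <- unname(auDuplex)
  }
  ## bent DNA: analyse per contiguous window
  units <- unlist(lapply(units, .splitDuplexWindows,
                         window = config$windowSize), recursive = FALSE)
  crossovers <- findCrossovers(units, maxDistance = config$maxInteraxial,
                               minOverlap = config$minOverlap,
                               curvatureThreshold = config$curvatureRmsd)
  ionPool <- .expandIons(model, copies)
  reports <- lapply(crossovers, function(cx) {
    rep <- classifyMode(cx, penetrationRadius = config$penetrationRadius,
                        insertionHalfWidth = config$insertionHalfWidth)
    rep <- detectAnchorContacts(rep, hbondCutoff = config$hbondCutoff,
                                proximalWindow = config$proximalWindow)
    detectCationBridges(rep, ionPool, cutoff = config$bridgeCutoff)
  })
  sg <- if (!is.null(model@cell)) model@cell@spaceGroup else ""
  rows <- lapply(reports, function(rp) {
    cx <- rp@crossover
    data.frame(
      mode = .modePretty[[rp@mode]],
      space_group = sg,
      sequence = .markupSequence(rp),
      cation = .cationLabel(rp@bridges),
      crossing_angle_deg = as.integer(round(cx@alphaDeg)),
      entry_id = entryId,
      alpha_exact = cx@alphaDeg,
      distance = cx@distance,
      provenance = paste(.duplexProvenance(cx@duplexA),
                         .duplexProvenance(cx@duplexB), sep = " x "),
      low_confidence = cx@lowConfidence,
      n_anchors = nrow(rp@anchors),
      n_bridges = nrow(rp@bridges),
      stringsAsFactors = FALSE)
  })
  table <- if (length(rows)) do.call(rbind, rows) else .emptyTable()
  if (nrow(table)) {
    ord <- order(table$mode, -table$alpha_exact)
    table <- table[ord, , drop = FALSE]
    reports <- reports[ord]
    rownames(table) <- NULL
  }
  structure(list(table = table, reports = reports, model = model,
                 config = config, entryId = entryId),
            class = "CrossoverAnalysis")
}

.emptyTable <- function() {
  data.frame(mode = character(), space_group = character(),
             sequence = character(), cation = character(),
             crossing_angle_deg = integer(), entry_id = character(),
             alpha_exact = numeric(), distance = numeric(),
             provenance = character(), low_confidence = logical(),
             n_anchors = integer(), n_bridges = integer(),
             stringsAsFactors = FALSE)
}

.emptyAnalysis <- function(model, entryId) {
  structure(list(table = .emptyTable(), reports = list(), model = model,
                 config = runConfig(), entryId = entryId),
            class = "CrossoverAnalysis")
}

#' @export
print.CrossoverAnalysis <- function(x, ...) {
  cat("CrossoverAnalysis of", x$entryId, "-", nrow(x$table), "crossover(s)\n")
  if (nrow(x$table))
    print(x$table[, c("mode", "sequence", "cation", "crossing_angle_deg",
                      "distance")], ...)
  invisible(x)
}

#' Batch crossover analysis with a sign-by-mode summary
#'
#' Analyses each entry of a manifest and concatenates the report rows. The
#' summary tabulates crossing-angle sign against interaction-mode class
#' (self-fitted groove-backbone vs groove-groove juxtaposition) and lists
#' any row violating the qualitative law that groove-backbone crossovers
#' are right-handed (positive) and groove-groove crossovers left-handed
#' (negative). Per-entry failures are recorded and skipped, not hidden.
#'
#' @param paths character vector of structure file paths (or a list mixing
#'   paths and \code{CrystalModel}s).
#' @param config a \code{\link{runConfig}}.
#' @return list with \code{table}, \code{contingency} (2x2 matrix:
#'   mode class x sign), \code{violations} (rows breaking the sign law),
#'   \code{failures} (named character of per-entry errors), and
#'   \code{status} (0 ok, 1 partial failure).
#' @export
batchAnalyze <- function(paths, config = runConfig()) {
  if (!length(paths)) stop("empty manifest: nothing to analyse")
  tables <- list()
  failures <- character()
  for (i in seq_along(paths)) {
    p <- if (is.list(paths)) paths[[i]] else paths[i]
    id <- if (is.character(p)) sub("\\.[^.]+$", "", basename(p)) else
      paste0("entry", i)
    res <- tryCatch(analyzeStructure(p, config = config, entryId = id),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      next
    }
    tables[[length(tables) + 1L]] <- res$table
  }
  table <- if (length(tables)) do.call(rbind, tables) else .emptyTable()
  gb <- grepl("groove/backbone", table$mode)
  gg <- grepl("<>", table$mode)
  pos <- table$alpha_exact > 0
  contingency <- matrix(
    c(sum(gb & pos), sum(gb & !pos), sum(gg & pos), sum(gg & !pos)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("groove-backbone", "groove-groove"),
                    c("positive", "negative")))
  violations <- table[(gb & !pos) | (gg & pos), , drop = FALSE]
  list(table = table, contingency = contingency, violations = violations,
       failures = failures, status = if (length(failures)) 1L else 0L)
}

#' Write an analysis table to TSV or JSON
#'
#' TSV output is byte-deterministic for identical inputs and configuration.
#'
#' @param result a \code{CrossoverAnalysis} or the result of
#'   \code{\link{batchAnalyze}} (anything with a \code{table} element).
#' @param path output file.
#' @param format "tsv" or "json".
#' @return \code{path}, invisibly.
#' @export
writeCrossoverReport <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- result$table
  if (format == "tsv") {
    out <- tab
    out$alpha_exact <- sprintf("%.6f", out$alpha_exact)
    out$distance <- sprintf("%.6f", out$distance)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  } else {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
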