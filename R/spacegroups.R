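#' @include AllClasses.R
NULL

#' Parse an xyz-triplet symmetry operator
#'
#' Converts operator strings such as \code{"-y,x-y,z+1/3"} into a
#' \code{\link{SymmetryOperator}} (rotation matrix plus translation in the
#' fractional frame). \code{symopLabel} is the inverse operation;
#' \code{parseSymop(symopLabel(op))} reproduces \code{op} exactly.
#'
#' @param label character(1), e.g. \code{"x+1/2,-y,z"}.
#' @return a \code{SymmetryOperator}.
#' @examples
#' op <- parseSymop("-y,x-y,z+1/3")
#' op@rot
#' symopLabel(op)
#' @export
parseSymop <- function(label) {
  parts <- strsplit(tolower(gsub("[[:space:]]", "", label)), ",")[[1]]
  if (length(parts) != 3)
    stop("operator string must have three comma-separated components: ", label)
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    ## tokenize into signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        rot[i, match(body, c("x", "y", "z"))] <-
          rot[i, match(body, c("x", "y", "z"))] + sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        f <- as.numeric(strsplit(body, "/")[[1]])
        trans[i] <- trans[i] + sgn * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[i] <- trans[i] + sgn * as.numeric(body)
      } else {
        stop("cannot parse operator term '", tok, "' in: ", label)
      }
    }
  }
  new("SymmetryOperator", rot = rot, trans = trans,
      label = .formatSymop(rot, trans))
}

#' @rdname parseSymop
#' @param op a \code{SymmetryOperator}.
#' @export
symopLabel <- function(op) .formatSymop(op@rot, op@trans)

## canonical "x-y,z+1/3" style formatting; translations snapped to /12 grid
.formatSymop <- function(rot, trans) {
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      co <- rot[i, j]
      if (abs(co) < 1e-9) next
      sgn <- if (co > 0) "+" else "-"
      s <- paste0(s, sgn, axes[j])
    }
    tr <- trans[i] %% 1
    num <- round(tr * 12)
    if (num %% 12 != 0) {
      g <- .gcd(num, 12)
      s <- paste0(s, "+", num / g, "/", 12 / g)
    }
    s <- sub("^\\+", "", s)
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

## ---- internal space-group table ----

.sgTableEnv <- new.env(parent = emptyenv())

.spaceGroupTable <- function() {
  if (!is.null(.sgTableEnv$table)) return(.sgTableEnv$table)
  path <- system.file("extdata", "spacegroups.txt", package = "DNACrossover")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  tab <- list()
  cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "[")) {
      name <- sub("^\\[([^]]+)\\].*$", "\\1", ln)
      aliases <- character()
      if (grepl("aliases:", ln))
        aliases <- strsplit(trimws(sub(".*aliases:", "", ln)), "[[:space:]]+")[[1]]
      cur <- name
      tab[[cur]] <- list(name = name, aliases = aliases, ops = character())
    } else {
      if (is.null(cur)) stop("malformed space-group table near: ", ln)
      tab[[cur]]$ops <- c(tab[[cur]]$ops, ln)
    }
  }
  .sgTableEnv$table <- tab
  tab
}

.normalizeSg <- function(symbol) toupper(gsub("[[:space:]_]", "", symbol))

#' Look up symmetry operators for a space group
#'
#' Returns the full list of symmetry-equivalent positions (including
#' centring translations) for a Hermann-Mauguin symbol, from the internal
#' plain-text table. Underscores and spacing in the symbol are ignored, so
#' \code{"R3"}, \code{"R 3"} and \code{"P3_1_21"} are all accepted.
#'
#' @param symbol Hermann-Mauguin space-group symbol.
#' @return list of \code{SymmetryOperator}.
#' @examples
#' length(spaceGroupOperators("P 21 21 21"))
#' @export
spaceGroupOperators <- function(symbol) {
  tab <- .spaceGroupTable()
  key <- .normalizeSg(symbol)
  for (entry in tab) {
    if (key %in% .normalizeSg(c(entry$name, entry$aliases)))
      return(lapply(entry$ops, parseSymop))
  }
  stop("operators unavailable: space group '", symbol,
       "' is not in the internal table and the file provided none")
}

#' Names of all space groups in the internal operator table
#' @return character vector of Hermann-Mauguin symbols.
#' @export
knownSpaceGroups <- function() {
  vapply(.spaceGroupTable(), function(e) e$name, character(1), USE.NAMES = FALSE)
}
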