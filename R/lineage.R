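## Sulston nomenclature engine: name parsing, parent/daughter algebra,
## wildcard pattern search, descendant expansion over observed cells.

# founder prefixes, longest first so prefix matching picks "EMS" over "E"
.FOUNDERS <- c("EMS", "P0", "P1", "P2", "P3", "P4", "AB", "MS",
               "Z2", "Z3", "C", "D", "E")
.DIV_LETTERS <- c("a", "p", "l", "r", "d", "v")

# embryonic founder pedigree (suffix-free names)
.FOUNDER_PARENT <- c(AB = "P0", P1 = "P0", EMS = "P1", P2 = "P1",
                     MS = "EMS", E = "EMS", C = "P2", P3 = "P2",
                     D = "P3", P4 = "P3", Z2 = "P4", Z3 = "P4")

.FOUNDER_DAUGHTERS <- list(P0 = c("AB", "P1"), P1 = c("EMS", "P2"),
                           EMS = c("MS", "E"), P2 = c("C", "P3"),
                           P3 = c("D", "P4"), P4 = c("Z2", "Z3"),
                           Z2 = character(), Z3 = character())

# strict founder-level ancestor chains (founder itself excluded)
.FOUNDER_ANCESTORS <- local({
  out <- list()
  for (f in .FOUNDERS) {
    chain <- character()
    cur <- f
    while (!is.na(cur <- unname(.FOUNDER_PARENT[cur])[1L]))
      chain <- c(chain, cur)
    out[[f]] <- chain
  }
  out
})

# canonical sibling order: a<p, d<v, l<r
.LETTER_RANK <- c(a = 1, d = 1, l = 1, p = 2, v = 2, r = 2)

#' Parse Sulston cell names
#'
#' Splits each name into its founder prefix (the longest match among P0-P4,
#' AB, EMS, MS, E, C, D, Z2, Z3) and a suffix of division letters
#' (a/p, l/r, d/v). Names that do not fit the nomenclature (e.g.
#' \code{"polar body"}) are literal labels: they are retained in tables and
#' plots but excluded from lineage algebra.
#'
#' @param x character vector of cell names.
#' @param wildcard if TRUE, also accept \code{'x'} in the suffix (pattern
#'   syntax; \code{'x'} matches any single division letter).
#' @return data.frame with columns \code{name}, \code{founder},
#'   \code{suffix}, \code{parseable}.
#' @examples
#' parseLineageName(c("ABal", "EMS", "Ea", "polar body"))
#' @export
parseLineageName <- function(x, wildcard = FALSE) {
  x <- as.character(x)
  founder <- rep(NA_character_, length(x))
  suffix <- rep(NA_character_, length(x))
  letters_ok <- .DIV_LETTERS
  if (wildcard) letters_ok <- c(letters_ok, "x")
  for (f in .FOUNDERS) {
    hit <- is.na(founder) & startsWith(x, f)
    founder[hit] <- f
    suffix[hit] <- substring(x[hit], nchar(f) + 1L)
  }
  ok <- !is.na(founder) & !is.na(suffix)
  chk <- ok & nzchar(suffix)
  if (any(chk)) {
    valid_sfx <- vapply(strsplit(suffix[chk], ""), function(s)
      all(s %in% letters_ok), logical(1))
    ok[chk][!valid_sfx] <- FALSE
  }
  founder[!ok] <- NA_character_
  suffix[!ok] <- NA_character_
  data.frame(name = x, founder = founder, suffix = suffix,
             parseable = ok, stringsAsFactors = FALSE)
}

#' @rdname parseLineageName
#' @export
isLineageName <- function(x) parseLineageName(x)$parseable

#' Parent of a Sulston name
#'
#' For suffixed names the last division letter is stripped; suffix-free
#' founders follow the embryonic pedigree (AB,P1 -> P0; EMS,P2 -> P1;
#' MS,E -> EMS; C,P3 -> P2; D,P4 -> P3; Z2,Z3 -> P4). The zygote P0 has no
#' parent and maps to \code{NA} silently; literal labels are "unknown" and
#' map to \code{NA} with a warning.
#'
#' @param x character vector of cell names.
#' @return character vector of parent names (NA for P0 and for literals).
#' @examples
#' parentOf(c("ABal", "MS", "P0"))
#' @export
parentOf <- function(x) {
  p <- parseLineageName(x)
  out <- rep(NA_character_, length(x))
  if (any(!p$parseable))
    warning(sprintf("unknown (literal) cell label(s): %s",
                    paste(unique(p$name[!p$parseable]), collapse = ", ")))
  has_sfx <- p$parseable & nzchar(p$suffix)
  out[has_sfx] <- paste0(p$founder[has_sfx],
                         substr(p$suffix[has_sfx], 1L,
                                nchar(p$suffix[has_sfx]) - 1L))
  bare <- p$parseable & !nzchar(p$suffix)
  out[bare] <- unname(.FOUNDER_PARENT[p$name[bare]])  # NA for P0
  out
}

#' Daughters of a Sulston name
#'
#' Founder cells follow the pedigree (P0 -> AB, P1; EMS -> MS, E; ...;
#' Z2 and Z3 are terminal). For letter-dividing cells the observed daughters
#' are returned when an \linkS4class{EmbryoTable} (or character vector of
#' observed names) is supplied; otherwise the nomenclaturally possible set
#' \{name+a, name+p, name+l, name+r, name+d, name+v\}, flagged with
#' \code{attr(, "potential") = TRUE}.
#'
#' @param x a single cell name.
#' @param observed optional EmbryoTable or character vector of observed
#'   cell names restricting the answer to observed daughters.
#' @return character vector of daughter names.
#' @examples
#' daughtersOf("P2")
#' daughtersOf("Ca")
#' daughtersOf("Ca", observed = c("Caa", "Cap", "Cpp"))
#' @export
daughtersOf <- function(x, observed = NULL) {
  stopifnot(length(x) == 1L)
  p <- parseLineageName(x)
  if (!p$parseable) {
    warning(sprintf("unknown (literal) cell label: %s", x))
    return(character())
  }
  if (is(observed, "EmbryoTable")) observed <- cellNames(observed)
  if (!nzchar(p$suffix) && p$name %in% names(.FOUNDER_DAUGHTERS)) {
    kids <- .FOUNDER_DAUGHTERS[[p$name]]
    if (!is.null(observed)) kids <- intersect(kids, observed)
    return(kids)
  }
  if (!is.null(observed)) {
    obs <- parseLineageName(observed)
    cand <- observed[obs$parseable & obs$founder == p$founder &
                       nchar(obs$suffix) == nchar(p$suffix) + 1L &
                       startsWith(obs$suffix, p$suffix)]
    return(unique(cand))
  }
  kids <- paste0(x, .DIV_LETTERS)
  attr(kids, "potential") <- TRUE
  kids
}

#' Test lineage descent
#'
#' TRUE when repeatedly taking \code{\link{parentOf}} from \code{x} reaches
#' \code{ancestor}. Literal labels are never descendants (a warning is
#' raised).
#'
#' @param x character vector of cell names.
#' @param ancestor single candidate ancestor name.
#' @param inclusive if TRUE (default) a cell counts as its own descendant.
#' @return logical vector.
#' @examples
#' isDescendant("Cap", "P2")
#' isDescendant("MS", "AB")
#' @export
isDescendant <- function(x, ancestor, inclusive = TRUE) {
  stopifnot(length(ancestor) == 1L)
  pa <- parseLineageName(ancestor)
  if (!pa$parseable) {
    warning(sprintf("unknown (literal) ancestor label: %s", ancestor))
    return(rep(FALSE, length(x)))
  }
  px <- parseLineageName(x)
  if (any(!px$parseable))
    warning(sprintf("unknown (literal) cell label(s): %s",
                    paste(unique(px$name[!px$parseable]), collapse = ", ")))
  # equivalent to walking parentOf: within a founder, ancestry is suffix
  # prefixing; across founders it can only pass through bare founder names
  same <- px$parseable & px$founder == pa$founder &
    startsWith(px$suffix, pa$suffix)
  cross <- px$parseable & !nzchar(pa$suffix) &
    vapply(px$founder, function(f)
      !is.na(f) && pa$name %in% .FOUNDER_ANCESTORS[[f]], logical(1),
      USE.NAMES = FALSE)
  res <- (same | cross) %in% TRUE
  if (!inclusive) res <- res & x != ancestor
  res
}

#' Match cell names against a Sulston wildcard pattern
#'
#' A pattern is a founder prefix plus division letters where \code{'x'}
#' stands for exactly one letter from a/p/l/r/d/v (so \code{"Cxp"} matches
#' Cap and Cpp but not Ca or Capp). A pattern without \code{'x'} is exact
#' equality. Literal labels never match.
#'
#' @param x character vector of cell names.
#' @param pattern a single pattern string.
#' @return logical vector.
#' @examples
#' matchLineage(c("Cap", "Cpp", "Ca", "Capa"), "Cxp")
#' @export
matchLineage <- function(x, pattern) {
  stopifnot(length(pattern) == 1L)
  pp <- parseLineageName(pattern, wildcard = TRUE)
  if (!pp$parseable)
    stop(sprintf("invalid lineage pattern: '%s'", pattern))
  px <- parseLineageName(x)
  out <- px$parseable & px$founder == pp$founder &
    nchar(px$suffix) == nchar(pp$suffix)
  out[is.na(out)] <- FALSE
  if (nzchar(pp$suffix) && any(out)) {
    pat_l <- strsplit(pp$suffix, "")[[1L]]
    idx <- which(out)
    keep <- vapply(strsplit(px$suffix[idx], ""), function(s)
      all(pat_l == "x" | pat_l == s), logical(1))
    out[idx] <- keep
  }
  out
}

#' Select observed cells by lineage patterns
#'
#' The union over patterns of observed names matching each pattern, plus
#' (optionally) every observed descendant of a match. A pattern matching
#' nothing contributes the empty set with a warning, not an error. Matching
#' is deterministic and order-independent; the result is sorted.
#'
#' @param x an \linkS4class{EmbryoTable} or character vector of observed
#'   cell names.
#' @param patterns character vector of Sulston patterns (may use 'x').
#' @param includeDescendants also include observed descendants of each
#'   matched cell.
#' @return sorted character vector of selected cell names.
#' @examples
#' obs <- c("Ca", "Cp", "Cap", "Cpp", "Capa")
#' selectCells(obs, "Cxp")
#' selectCells(obs, "Cxp", includeDescendants = TRUE)
#' @export
selectCells <- function(x, patterns, includeDescendants = FALSE) {
  if (is(x, "EmbryoTable")) x <- cellNames(x)
  x <- unique(as.character(x))
  if (!length(patterns)) return(character())
  hits <- character()
  for (pat in patterns) {
    m <- x[matchLineage(x, pat)]
    if (!length(m))
      warning(sprintf("pattern '%s' matched no observed cells", pat))
    hits <- union(hits, m)
  }
  if (includeDescendants && length(hits)) {
    px <- parseLineageName(x)
    desc <- vapply(seq_along(x), function(i) {
      if (!px$parseable[i]) return(FALSE)
      cur <- x[i]
      repeat {
        if (cur %in% hits) return(TRUE)
        cur <- suppressWarnings(parentOf(cur))
        if (is.na(cur)) return(FALSE)
      }
    }, logical(1))
    hits <- union(hits, x[desc])
  }
  sort(hits)
}

# TRUE when the name itself or any ancestor matches one of the patterns;
# used for "lineage" membership (e.g. landmark groups) where the matched
# cells may already have divided by the time of interest
.inLineageOf <- function(x, patterns) {
  x <- as.character(x)
  vapply(x, function(nm) {
    if (!isLineageName(nm)) return(FALSE)
    cur <- nm
    repeat {
      for (pat in patterns) if (matchLineage(cur, pat)) return(TRUE)
      cur <- suppressWarnings(parentOf(cur))
      if (is.na(cur)) return(FALSE)
    }
  }, logical(1), USE.NAMES = FALSE)
}

# canonical display order for a set of sibling names (a<p, d<v, l<r;
# founder pairs per the pedigree)
.FOUNDER_ORDER <- c(P0 = 0, AB = 1, P1 = 2, EMS = 3, P2 = 4, MS = 5, E = 6,
                    C = 7, P3 = 8, D = 9, P4 = 10, Z2 = 11, Z3 = 12)

orderSiblings <- function(kids) {
  if (length(kids) <= 1L) return(kids)
  p <- parseLineageName(kids)
  key <- ifelse(nzchar(p$suffix),
                .LETTER_RANK[substr(p$suffix, nchar(p$suffix),
                                    nchar(p$suffix))],
                .FOUNDER_ORDER[kids])
  kids[order(key, kids)]
}
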