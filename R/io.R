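## Readers and writers for the three file dialects produced around the
## StarryNite/AceTree pipeline, plus pixel->micron / ordinal->minutes
## conversion.

.CD_REQUIRED <- c("cell", "time", "x", "y", "z")

#' Read a CD-format tracking file
#'
#' CD files are comma-separated text with a header line; required columns
#' are \code{cell}, \code{time}, \code{x}, \code{y} and \code{z} (matched
#' case-insensitively with surrounding whitespace stripped, since files
#' originate from several legacy exporters). Any further numeric columns
#' are kept; those other than \code{diameter} are treated as expression
#' columns (the conventional default is \code{blot}).
#'
#' Coordinates are taken as raw pixels (x, y) and plane units (z), time as
#' ordinal frame indices; convert with \code{\link{applyMetadata}}.
#'
#' @param path path to the file.
#' @param exprColumns optional explicit expression-column selection.
#' @param embryoId label for the recording; defaults to the file name
#'   without extension.
#' @return an \linkS4class{EmbryoTable} (units pixel, time ordinal).
#' @seealso \code{\link{writeCD}}, \code{\link{applyMetadata}}
#' @export
readCD <- function(path, exprColumns = NULL, embryoId = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(embryoId))
    embryoId <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, strip.white = TRUE,
                         colClasses = "character")
  names(raw) <- trimws(names(raw))
  lower <- tolower(names(raw))
  for (col in .CD_REQUIRED) {
    if (!(col %in% lower))
      stop(sprintf("CD format error in %s: missing required column '%s'",
                   basename(path), col))
  }
  names(raw) <- ifelse(lower %in% .CD_REQUIRED, lower, names(raw))
  numeric_cols <- setdiff(names(raw), "cell")
  d <- raw
  for (col in numeric_cols) {
    v <- trimws(d[[col]])
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & nzchar(v))
    if (length(bad))
      stop(sprintf(
        "CD format error in %s: unparseable value '%s' in column '%s' (data row %d)",
        basename(path), v[bad[1L]], col, bad[1L]))
    num[!nzchar(v)] <- NA_real_   # empty field = value absent, not 0
    d[[col]] <- num
  }
  d$cell <- trimws(d$cell)
  key <- paste(d$cell, d$time, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("CD format error in %s: duplicate (cell, time) = (%s, %g)",
                 basename(path), d$cell[i], d$time[i]))
  }
  ord <- c(.CD_REQUIRED, setdiff(names(d), .CD_REQUIRED))
  # time axes that have been event-aligned (zero/negative or fractional
  # times) are recognised as such rather than rejected as bad ordinals
  tu <- if (nrow(d) && (any(d$time < 1) || any(d$time != round(d$time))))
    "aligned" else "ordinal"
  EmbryoTable(d[, ord, drop = FALSE], embryoId = embryoId,
              coordUnits = "pixel", timeUnits = tu,
              exprColumns = exprColumns)
}

#' Write an EmbryoTable as a CD file
#'
#' Columns are emitted in the canonical order cell, time, x, y, z followed
#' by the remaining stored columns; numeric values keep full precision
#' (>= 6 significant digits) and missing expression values are written as
#' empty fields. Line endings are UNIX.
#'
#' @param table an \linkS4class{EmbryoTable}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @seealso \code{\link{readCD}}
#' @export
writeCD <- function(table, path) {
  stopifnot(is(table, "EmbryoTable"))
  d <- cdData(table)
  ord <- c(.CD_REQUIRED, setdiff(names(d), .CD_REQUIRED))
  d <- d[, ord, drop = FALSE]
  out <- lapply(d, function(col) {
    if (is.numeric(col)) {
      s <- vapply(col, function(v)
        if (is.na(v)) "" else formatC(v, format = "g", digits = 15),
        character(1))
      s
    } else as.character(col)
  })
  lines <- c(paste(names(d), collapse = ","),
             if (nrow(d)) do.call(paste, c(out, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a raw StarryNite zip archive
#'
#' Parses the per-timepoint nuclei files inside a StarryNite \code{.zip}.
#' The supported dialect is comma-separated records with, in order: index,
#' valid flag, predecessor index, two successor indices, x, y, z, diameter,
#' identity name, and a trailing expression value (mapped to column
#' \code{blot}). The timepoint is the first numeric run in each nuclei
#' file's name (\code{t042-nuclei} -> 42). Only nuclei with a non-zero
#' valid flag produce rows. Other layouts are rejected loudly.
#'
#' @param path path to the .zip archive.
#' @param embryoId label; defaults to the archive name.
#' @return an \linkS4class{EmbryoTable} (units pixel, time ordinal).
#' @export
readStarryNiteZip <- function(path, embryoId = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(embryoId))
    embryoId <- sub("\\.[^.]*$", "", basename(path))
  listing <- utils::unzip(path, list = TRUE)
  nuc <- listing$Name[grepl("nuclei", basename(listing$Name),
                            ignore.case = TRUE) &
                        !grepl("/$", listing$Name)]
  if (!length(nuc))
    stop(sprintf("StarryNite format error in %s: no nuclei files found",
                 basename(path)))
  tmp <- tempfile("snzip")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, files = nuc, exdir = tmp, junkpaths = FALSE)
  rows <- vector("list", length(nuc))
  for (i in seq_along(nuc)) {
    fname <- basename(nuc[i])
    trun <- regmatches(fname, regexpr("[0-9]+", fname))
    if (!length(trun))
      stop(sprintf(
        "StarryNite format error: no timepoint index in file name '%s'",
        fname))
    tp <- as.integer(trun)
    lines <- readLines(file.path(tmp, nuc[i]), warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) next
    parsed <- lapply(seq_along(lines), function(j) {
      f <- trimws(strsplit(lines[j], ",", fixed = TRUE)[[1L]])
      if (length(f) < 11L)
        stop(sprintf(
          "StarryNite format error in %s line %d: expected >= 11 fields, got %d",
          fname, j, length(f)))
      num <- suppressWarnings(as.numeric(f[c(2L, 6L, 7L, 8L, 9L, 11L)]))
      if (anyNA(num[1:5]))
        stop(sprintf(
          "StarryNite format error in %s line %d: unparseable numeric field",
          fname, j))
      list(valid = num[1L], x = num[2L], y = num[3L], z = num[4L],
           diameter = num[5L], blot = num[6L], cell = f[10L])
    })
    keep <- vapply(parsed, function(p) p$valid != 0, logical(1))
    parsed <- parsed[keep]
    if (!length(parsed)) next
    rows[[i]] <- data.frame(
      cell = vapply(parsed, `[[`, character(1), "cell"),
      time = tp,
      x = vapply(parsed, `[[`, numeric(1), "x"),
      y = vapply(parsed, `[[`, numeric(1), "y"),
      z = vapply(parsed, `[[`, numeric(1), "z"),
      blot = vapply(parsed, `[[`, numeric(1), "blot"),
      diameter = vapply(parsed, `[[`, numeric(1), "diameter"),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(d))
    d <- data.frame(cell = character(), time = numeric(), x = numeric(),
                    y = numeric(), z = numeric(), blot = numeric(),
                    diameter = numeric(), stringsAsFactors = FALSE)
  d <- d[order(d$time, d$cell), , drop = FALSE]
  EmbryoTable(d, embryoId = embryoId, coordUnits = "pixel",
              timeUnits = "ordinal")
}

#' Read a TIME file
#'
#' Two-column comma- (or whitespace-) separated text mapping ordinal
#' timepoints to elapsed minutes. A single header line is auto-detected
#' (first line with a non-numeric first field). Elapsed times must be
#' strictly increasing.
#'
#' @param path path to the file.
#' @return a \linkS4class{TimeMap}.
#' @export
readTimeFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("TIME format error in %s: empty file",
                                   basename(path)))
  split1 <- function(s) {
    f <- strsplit(trimws(s), "[,\t ]+")[[1L]]
    f[nzchar(f)]
  }
  first <- split1(lines[1L])
  has_header <- is.na(suppressWarnings(as.numeric(first[1L])))
  if (has_header) lines <- lines[-1L]
  if (!length(lines))
    stop(sprintf("TIME format error in %s: no data rows", basename(path)))
  ords <- numeric(length(lines)); mins <- numeric(length(lines))
  for (j in seq_along(lines)) {
    f <- split1(lines[j])
    if (length(f) < 2L)
      stop(sprintf("TIME format error in %s line %d: expected 2 columns",
                   basename(path), j + has_header))
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(v))
      stop(sprintf("TIME format error in %s line %d: unparseable value",
                   basename(path), j + has_header))
    ords[j] <- v[1L]; mins[j] <- v[2L]
  }
  ix <- order(ords)
  ords <- ords[ix]; mins <- mins[ix]
  if (anyDuplicated(ords))
    stop(sprintf("TIME format error in %s: duplicate ordinal timepoint",
                 basename(path)))
  if (is.unsorted(mins, strictly = TRUE))
    stop(sprintf(
      "TIME format error in %s: elapsed times are not strictly increasing",
      basename(path)))
  TimeMap(ords, mins)
}

#' Write a TimeMap as a TIME file
#'
#' @param timeMap a \linkS4class{TimeMap}.
#' @param path output path.
#' @param header write a header line (default TRUE).
#' @return invisibly, \code{path}.
#' @export
writeTimeFile <- function(timeMap, path, header = TRUE) {
  stopifnot(is(timeMap, "TimeMap"))
  lines <- c(if (header) "time,minutes",
             paste(timeMap@ordinal,
                   formatC(timeMap@minutes, format = "g", digits = 17),
                   sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Convert a pixel/ordinal table to microns and elapsed minutes
#'
#' Scales x and y by the xy resolution and z by the plane spacing, setting
#' the units flag to micron. If the metadata carries a time map, ordinal
#' timepoints are converted to elapsed minutes, with the original ordinal
#' retained in an auxiliary \code{ordinal} column. Applying metadata to a
#' table already in microns is an error, never a silent re-scale.
#'
#' @param table an \linkS4class{EmbryoTable} in pixel units.
#' @param meta an \linkS4class{EmbryoMetadata}.
#' @return the converted \linkS4class{EmbryoTable}.
#' @examples
#' d <- data.frame(cell = "ABa", time = 1, x = 100, y = 50, z = 10)
#' tb <- EmbryoTable(d)
#' cdData(applyMetadata(tb, EmbryoMetadata(0.1, 1)))
#' @export
applyMetadata <- function(table, meta) {
  stopifnot(is(table, "EmbryoTable"), is(meta, "EmbryoMetadata"))
  if (coordUnits(table) != "pixel")
    stop("table is already in micron units; refusing to re-scale")
  d <- cdData(table)
  d$x <- d$x * meta@xyRes
  d$y <- d$y * meta@xyRes
  d$z <- d$z * meta@zRes
  tu <- timeUnits(table)
  if (!is.null(meta@timeMap) && identical(tu, "ordinal")) {
    tm <- meta@timeMap
    ix <- match(d$time, tm@ordinal)
    if (anyNA(ix)) {
      missing_t <- sort(unique(d$time[is.na(ix)]))
      stop(sprintf("ordinal timepoint(s) absent from time map: %s",
                   paste(missing_t, collapse = ", ")))
    }
    d$ordinal <- d$time
    d$time <- tm@minutes[ix]
    tu <- "minutes"
  }
  EmbryoTable(d, embryoId = embryoId(table), coordUnits = "micron",
              timeUnits = tu, exprColumns = exprColumns(table))
}
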