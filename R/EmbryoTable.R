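#' Construct an EmbryoTable
#'
#' Builds a validated \linkS4class{EmbryoTable} from a long-format
#' data.frame with one row per tracked (cell, time) observation.
#'
#' @param data data.frame with columns \code{cell}, \code{time}, \code{x},
#'   \code{y}, \code{z}; additional numeric columns are kept.
#' @param embryoId label identifying the recording.
#' @param coordUnits \code{"pixel"} (raw tracker pixels/planes) or
#'   \code{"micron"}.
#' @param timeUnits \code{"ordinal"}, \code{"minutes"} or \code{"aligned"}.
#' @param exprColumns names of the quantitative expression columns. Default:
#'   every extra numeric column except \code{diameter} and \code{ordinal}.
#' @return an \linkS4class{EmbryoTable}.
#' @examples
#' d <- data.frame(cell = "ABa", time = 5, x = 100, y = 120, z = 10,
#'                 blot = 250)
#' EmbryoTable(d, embryoId = "demo")
#' @export
EmbryoTable <- function(data, embryoId = "embryo", coordUnits = "pixel",
                        timeUnits = "ordinal", exprColumns = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if ("cell" %in% names(data)) data$cell <- as.character(data$cell)
  if (is.null(exprColumns)) {
    extra <- setdiff(names(data),
                     c("cell", "time", "x", "y", "z", "diameter", "ordinal"))
    exprColumns <- extra[vapply(data[extra], is.numeric, logical(1))]
  }
  rownames(data) <- NULL
  new("EmbryoTable", data = data, embryoId = embryoId,
      coordUnits = coordUnits, timeUnits = timeUnits,
      exprColumns = as.character(exprColumns))
}

#' @describeIn EmbryoTable the underlying data.frame.
#' @param x an EmbryoTable.
#' @export
setMethod("cdData", "EmbryoTable", function(x) x@data)

#' @describeIn EmbryoTable the embryo identifier.
#' @export
setMethod("embryoId", "EmbryoTable", function(x) x@embryoId)

#' @describeIn EmbryoTable replace the embryo identifier.
#' @param value new identifier.
#' @export
setMethod("embryoId<-", "EmbryoTable", function(x, value) {
  x@embryoId <- as.character(value)
  validObject(x)
  x
})

#' @describeIn EmbryoTable coordinate units flag.
#' @export
setMethod("coordUnits", "EmbryoTable", function(x) x@coordUnits)

#' @describeIn EmbryoTable time units flag.
#' @export
setMethod("timeUnits", "EmbryoTable", function(x) x@timeUnits)

#' @describeIn EmbryoTable names of the expression columns.
#' @export
setMethod("exprColumns", "EmbryoTable", function(x) x@exprColumns)

#' @describeIn EmbryoTable distinct observed cell names.
#' @export
setMethod("cellNames", "EmbryoTable", function(x) unique(x@data$cell))

#' @describeIn EmbryoTable sorted distinct timepoints.
#' @export
setMethod("timePoints", "EmbryoTable", function(x) sort(unique(x@data$time)))

setMethod("show", "EmbryoTable", function(object) {
  d <- object@data
  cat(sprintf("EmbryoTable '%s': %d rows, %d cells, %d timepoints\n",
              object@embryoId, nrow(d), length(unique(d$cell)),
              length(unique(d$time))))
  cat(sprintf("  units: %s / %s", object@coordUnits, object@timeUnits))
  if (length(object@exprColumns))
    cat(sprintf("; expression: %s", paste(object@exprColumns, collapse = ", ")))
  cat("\n")
  invisible(object)
})

#' @export
setMethod("dim", "EmbryoTable", function(x) dim(x@data))

# internal: replace the data slot, revalidating
setEmbryoData <- function(x, data) {
  rownames(data) <- NULL
  x@data <- data
  validObject(x)
  x
}

#' Construct recording metadata
#'
#' @param xyRes microns per pixel in x and y (> 0).
#' @param zRes microns per imaging plane (> 0).
#' @param timeMap optional \linkS4class{TimeMap} from
#'   \code{\link{readTimeFile}}.
#' @return an \linkS4class{EmbryoMetadata}.
#' @examples
#' EmbryoMetadata(xyRes = 0.087, zRes = 0.504)
#' @export
EmbryoMetadata <- function(xyRes, zRes, timeMap = NULL) {
  new("EmbryoMetadata", xyRes = as.numeric(xyRes), zRes = as.numeric(zRes),
      timeMap = timeMap)
}

setMethod("show", "EmbryoMetadata", function(object) {
  cat(sprintf("EmbryoMetadata: xy %.4g um/px, z %.4g um/plane, %s time map\n",
              object@xyRes, object@zRes,
              if (is.null(object@timeMap)) "no" else
                sprintf("%d-entry", length(object@timeMap@ordinal))))
  invisible(object)
})

#' Construct a TimeMap
#'
#' @param ordinal integer frame indices (unique, increasing).
#' @param minutes elapsed minutes (strictly increasing).
#' @return a \linkS4class{TimeMap}.
#' @export
TimeMap <- function(ordinal, minutes) {
  new("TimeMap", ordinal = as.integer(ordinal), minutes = as.numeric(minutes))
}

setMethod("show", "TimeMap", function(object) {
  n <- length(object@ordinal)
  cat(sprintf("TimeMap: %d entries", n))
  if (n) cat(sprintf(" (t %d..%d -> %.4g..%.4g min)",
                     object@ordinal[1L], object@ordinal[n],
                     object@minutes[1L], object@minutes[n]))
  cat("\n")
  invisible(object)
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform fitted at t = %s\n",
              format(object@referenceTime)))
  cat("  center:", paste(format(object@center, digits = 5), collapse = " "),
      "\n  rotation:\n")
  print(round(object@rotation, 5))
  invisible(object)
})

setMethod("show", "DepthModel", function(object) {
  cat(sprintf(
    "DepthModel on '%s': k = %.5g /um, zRef = %.4g um (%d points, %d embryos)\n",
    object@exprColumn, object@decayRate, object@zRef, object@nPointsFit,
    length(object@scales)))
  invisible(object)
})

#' @describeIn DepthModel-class fitted decay rate (1/micron).
#' @param x a DepthModel.
#' @export
setMethod("decayRate", "DepthModel", function(x) x@decayRate)

#' @describeIn DepthModel-class reference depth (microns).
#' @export
setMethod("referenceDepth", "DepthModel", function(x) x@zRef)

setMethod("show", "TimeAlignment", function(object) {
  cat(sprintf("TimeAlignment on %s of %s: %d embryos\n",
              object@eventKind, object@eventCell, length(object@offsets)))
  if (length(object@offsets)) print(round(object@offsets, 4))
  invisible(object)
})

#' @describeIn TimeAlignment-class per-embryo additive offsets.
#' @param x a TimeAlignment.
#' @export
setMethod("alignmentOffsets", "TimeAlignment", function(x) x@offsets)

#' @describeIn TreeLayout-class per-cell layout table.
#' @param x a TreeLayout.
#' @export
setMethod("treeCells", "TreeLayout", function(x) x@cells)

setMethod("show", "TreeLayout", function(object) {
  cat(sprintf("TreeLayout rooted at %s: %d cells (%d leaves), window [%s, %s]\n",
              object@root, nrow(object@cells), sum(object@cells$leaf),
              format(object@window[1L]), format(object@window[2L])))
  invisible(object)
})
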