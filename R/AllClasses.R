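#' @import methods
NULL

.COORD_UNITS <- c("pixel", "micron")
.TIME_UNITS  <- c("ordinal", "minutes", "aligned")

#' Tracked-embryo table
#'
#' One row per (cell, time) observation of a tracked nucleus, with 3D
#' position, optional quantitative reporter columns (default \code{"blot"})
#' and an optional nuclear \code{diameter}. Coordinates are either raw
#' pixels/planes straight from the tracker or microns after
#' \code{\link{applyMetadata}}; the \code{coordUnits} flag records which.
#' The time axis is an ordinal frame index, elapsed minutes, or a signed
#' event-aligned axis (\code{timeUnits}).
#'
#' @slot data data.frame with columns \code{cell}, \code{time}, \code{x},
#'   \code{y}, \code{z} plus any quantitative columns.
#' @slot embryoId single string identifying the recording.
#' @slot coordUnits \code{"pixel"} or \code{"micron"}.
#' @slot timeUnits \code{"ordinal"}, \code{"minutes"} or \code{"aligned"}.
#' @slot exprColumns names of the quantitative expression columns.
#' @aliases EmbryoTable-class
#' @exportClass EmbryoTable
setClass("EmbryoTable",
  representation(
    data        = "data.frame",
    embryoId    = "character",
    coordUnits  = "character",
    timeUnits   = "character",
    exprColumns = "character"
  ),
  prototype(
    data = data.frame(cell = character(), time = numeric(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE),
    embryoId = "embryo", coordUnits = "pixel", timeUnits = "ordinal",
    exprColumns = character()
  )
)

setValidity("EmbryoTable", function(object) {
  d <- object@data
  msgs <- character()
  req <- c("cell", "time", "x", "y", "z")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (length(object@embryoId) != 1L || is.na(object@embryoId) ||
      !nzchar(object@embryoId))
    msgs <- c(msgs, "embryoId must be a single non-empty string")
  if (!(object@coordUnits %in% .COORD_UNITS))
    msgs <- c(msgs, "coordUnits must be 'pixel' or 'micron'")
  if (!(object@timeUnits %in% .TIME_UNITS))
    msgs <- c(msgs, "timeUnits must be 'ordinal', 'minutes' or 'aligned'")
  if (!is.character(d$cell))
    msgs <- c(msgs, "column 'cell' must be character")
  for (col in c("time", "x", "y", "z")) {
    if (!is.numeric(d[[col]]))
      msgs <- c(msgs, sprintf("column '%s' must be numeric", col))
  }
  if (nrow(d)) {
    if (anyNA(d$time) || any(!is.finite(d$time)))
      msgs <- c(msgs, "time values must be finite")
    else if (identical(object@timeUnits, "ordinal") &&
             (any(d$time < 1) || any(d$time != round(d$time))))
      msgs <- c(msgs, "ordinal times must be whole numbers >= 1")
    pos <- as.matrix(d[, c("x", "y", "z")])
    if (any(!is.finite(pos)))
      msgs <- c(msgs, "positions must be finite")
    key <- paste(d$cell, d$time, sep = "\r")
    if (anyDuplicated(key)) {
      first <- key[duplicated(key)][1L]
      parts <- strsplit(first, "\r", fixed = TRUE)[[1L]]
      msgs <- c(msgs, sprintf("duplicate (cell, time) pair: (%s, %s)",
                              parts[1L], parts[2L]))
    }
  }
  if (length(object@exprColumns)) {
    absent <- setdiff(object@exprColumns, names(d))
    if (length(absent))
      msgs <- c(msgs, sprintf("expression column(s) not in data: %s",
                              paste(absent, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Recording metadata for unit conversion
#'
#' Voxel dimensions (microns per pixel in xy, microns per imaging plane in z)
#' and an optional map from ordinal timepoints to elapsed minutes.
#'
#' @slot xyRes microns per pixel, > 0.
#' @slot zRes microns per plane, > 0.
#' @slot timeMap a \code{\linkS4class{TimeMap}} or NULL.
#' @aliases EmbryoMetadata-class
#' @exportClass EmbryoMetadata
setClass("EmbryoMetadata",
  representation(xyRes = "numeric", zRes = "numeric", timeMap = "ANY"),
  prototype(xyRes = 1, zRes = 1, timeMap = NULL)
)

setValidity("EmbryoMetadata", function(object) {
  msgs <- character()
  if (length(object@xyRes) != 1L || !is.finite(object@xyRes) ||
      object@xyRes <= 0)
    msgs <- c(msgs, "xyRes must be a single positive number")
  if (length(object@zRes) != 1L || !is.finite(object@zRes) ||
      object@zRes <= 0)
    msgs <- c(msgs, "zRes must be a single positive number")
  if (!is.null(object@timeMap) && !is(object@timeMap, "TimeMap"))
    msgs <- c(msgs, "timeMap must be a TimeMap or NULL")
  if (length(msgs)) msgs else TRUE
})

#' Ordinal-to-elapsed time map
#'
#' Pairs of (ordinal frame index, elapsed minutes) as read from a TIME file.
#' Ordinals are unique and sorted; elapsed times strictly increase.
#'
#' @slot ordinal integer frame indices.
#' @slot minutes elapsed minutes, strictly increasing.
#' @aliases TimeMap-class
#' @exportClass TimeMap
setClass("TimeMap",
  representation(ordinal = "integer", minutes = "numeric"),
  prototype(ordinal = integer(), minutes = numeric())
)

setValidity("TimeMap", function(object) {
  o <- object@ordinal; m <- object@minutes
  if (length(o) != length(m))
    return("ordinal and minutes must have equal length")
  if (length(o)) {
    if (anyNA(o) || anyNA(m) || any(!is.finite(m)))
      return("entries must be finite")
    if (is.unsorted(o, strictly = TRUE))
      return("ordinals must be unique and sorted increasing")
    if (is.unsorted(m, strictly = TRUE))
      return("elapsed minutes must be strictly increasing")
  }
  TRUE
})

#' Rigid-body transform to the canonical anatomical frame
#'
#' A centering translation plus a proper rotation taking raw micron
#' coordinates into the canonical frame: anterior = +x, left = +y,
#' dorsal = +z (right-handed). Positions map as
#' \code{rotation \%*\% (p - center)}.
#'
#' @slot center length-3 centroid subtracted before rotation (microns).
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot referenceTime the timepoint the transform was fitted at.
#' @aliases RigidTransform-class
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(center = "numeric", rotation = "matrix",
                 referenceTime = "numeric"),
  prototype(center = c(0, 0, 0), rotation = diag(3), referenceTime = NA_real_)
)

setValidity("RigidTransform", function(object) {
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    return("center must be a finite length-3 vector")
  R <- object@rotation
  if (!is.numeric(R) || !all(dim(R) == c(3L, 3L)))
    return("rotation must be a numeric 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthogonal (R'R = I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det = +1 within 1e-9)")
  TRUE
})

#' Exponential depth-attenuation model for reporter expression
#'
#' Fluorescence loss with imaging depth is modelled as
#' \code{E(z) = exp(a_i) * exp(-k z)} with one decay rate \code{k} shared
#' across replicate embryos and a per-embryo log-scale intercept
#' \code{a_i}. Application corrects expression to a common reference depth
#' \code{zRef} using only \code{k} (so the model transfers to embryos not in
#' the training set).
#'
#' @slot decayRate decay rate k in 1/micron.
#' @slot scales named per-embryo log-scale intercepts from the fit.
#' @slot zRef reference depth in microns.
#' @slot exprColumn the expression column the model was fitted on.
#' @slot nPointsFit number of positive-expression points used.
#' @aliases DepthModel-class
#' @exportClass DepthModel
setClass("DepthModel",
  representation(decayRate = "numeric", scales = "numeric", zRef = "numeric",
                 exprColumn = "character", nPointsFit = "integer"),
  prototype(decayRate = 0, scales = numeric(), zRef = 0,
            exprColumn = "blot", nPointsFit = 0L)
)

setValidity("DepthModel", function(object) {
  msgs <- character()
  if (length(object@decayRate) != 1L || !is.finite(object@decayRate))
    msgs <- c(msgs, "decayRate must be a single finite number")
  if (length(object@zRef) != 1L || !is.finite(object@zRef))
    msgs <- c(msgs, "zRef must be a single finite number")
  if (length(object@exprColumn) != 1L || !nzchar(object@exprColumn))
    msgs <- c(msgs, "exprColumn must be a single non-empty string")
  if (length(object@scales) && is.null(names(object@scales)))
    msgs <- c(msgs, "scales must be named by embryo id")
  if (length(msgs)) msgs else TRUE
})

#' Event-based time alignment across embryos
#'
#' Records the developmental event used (cell name plus birth/last-seen) and
#' the additive offset applied to each embryo's time axis so that the event
#' sits at time 0.
#'
#' @slot eventCell Sulston name of the event cell.
#' @slot eventKind \code{"birth"} or \code{"last"}.
#' @slot offsets named numeric: offset added to each embryo's times.
#' @aliases TimeAlignment-class
#' @exportClass TimeAlignment
setClass("TimeAlignment",
  representation(eventCell = "character", eventKind = "character",
                 offsets = "numeric"),
  prototype(eventCell = NA_character_, eventKind = "birth",
            offsets = numeric())
)

setValidity("TimeAlignment", function(object) {
  if (!(object@eventKind %in% c("birth", "last")))
    return("eventKind must be 'birth' or 'last'")
  if (length(object@offsets) && (is.null(names(object@offsets)) ||
                                 any(!is.finite(object@offsets))))
    return("offsets must be finite and named by embryo id")
  TRUE
})

#' Lineage-tree layout
#'
#' Geometry of a lineage chart: one vertical segment per cell spanning
#' [birth, last-seen] in the plotted window, branching at divisions. Leaves
#' get consecutive x positions in canonical sibling order (a<p, d<v, l<r);
#' each internal cell sits at the midpoint of its daughters.
#'
#' @slot cells data.frame with columns \code{cell}, \code{x}, \code{birth},
#'   \code{end}, \code{parent}, \code{leaf}.
#' @slot root the root cell name the layout was built from.
#' @slot window length-2 numeric time window.
#' @aliases TreeLayout-class
#' @exportClass TreeLayout
setClass("TreeLayout",
  representation(cells = "data.frame", root = "character",
                 window = "numeric"),
  prototype(cells = data.frame(), root = NA_character_,
            window = c(-Inf, Inf))
)

setValidity("TreeLayout", function(object) {
  d <- object@cells
  need <- c("cell", "x", "birth", "end", "parent", "leaf")
  if (!all(need %in% names(d)))
    return(sprintf("cells must have columns %s", paste(need, collapse = ", ")))
  if (nrow(d) && any(d$end < d$birth))
    return("each cell's end must be >= its birth")
  TRUE
})

#' Parameters for the synthetic-embryo simulator
#'
#' The stated world the simulator draws from: a stereotyped division
#' schedule, an ellipsoidal embryo, a rigid orientation applied to the
#' canonical frame, a lineage-specific expression program with exponential
#' depth attenuation (rate \code{decayRate}) and multiplicative lognormal
#' measurement noise.
#'
#' @slot schedule data.frame(cell, birth, division) of ordinal times;
#'   division is NA for terminal cells.
#' @slot semiAxes ellipsoid semi-axes in microns (AP, LR, DV).
#' @slot rotation 3x3 proper rotation applied to canonical positions.
#' @slot translation length-3 shift applied after rotation (microns).
#' @slot expressionProgram list of list(pattern, onset, level) rules;
#'   the first matching rule (with descendants) sets a cell's level.
#' @slot baseline expression level of cells matching no rule.
#' @slot decayRate depth decay rate k in 1/micron.
#' @slot noiseSigma lognormal sigma on the log scale.
#' @slot positionJitter s.d. of the isotropic placement jitter (microns).
#' @slot tEnd last simulated ordinal timepoint.
#' @slot exprColumn name of the expression column emitted.
#' @aliases SimulationParams-class
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(schedule = "data.frame", semiAxes = "numeric",
                 rotation = "matrix", translation = "numeric",
                 expressionProgram = "list", baseline = "numeric",
                 decayRate = "numeric", noiseSigma = "numeric",
                 positionJitter = "numeric", tEnd = "numeric",
                 exprColumn = "character")
)

setValidity("SimulationParams", function(object) {
  s <- object@schedule
  if (!all(c("cell", "birth", "division") %in% names(s)))
    return("schedule needs columns cell, birth, division")
  if (any(!is.na(s$division) & s$division < s$birth))
    return("division times must not precede birth")
  if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
    return("semiAxes must be 3 positive numbers")
  if (abs(det(object@rotation) - 1) > 1e-9 ||
      max(abs(crossprod(object@rotation) - diag(3))) > 1e-9)
    return("rotation must be a proper rotation matrix")
  if (object@noiseSigma < 0 || object@positionJitter < 0)
    return("noise scales must be non-negative")
  TRUE
})
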