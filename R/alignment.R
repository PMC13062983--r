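## Event-based developmental time alignment: shift each embryo's time axis
## so a shared lineage event (birth or last observation of a named cell)
## sits at time 0, giving a common axis for cross-embryo comparison.

#' Time of a developmental event in one embryo
#'
#' Events are name-appearance based: \code{"birth"} is the smallest time at
#' which the exact cell name is observed, \code{"last"} the largest (the
#' cell's division or disappearance). Returned in the table's current time
#' units.
#'
#' @param table an \linkS4class{EmbryoTable}.
#' @param cell exact cell name.
#' @param kind \code{"birth"} or \code{"last"}.
#' @return a single time value.
#' @examples
#' d <- data.frame(cell = "ABa", time = 4:6, x = 0, y = 0, z = 0)
#' eventTime(EmbryoTable(d), "ABa", "birth")
#' @export
eventTime <- function(table, cell, kind = c("birth", "last")) {
  stopifnot(is(table, "EmbryoTable"), length(cell) == 1L)
  kind <- match.arg(kind)
  times <- cdData(table)$time[cdData(table)$cell == cell]
  if (!length(times))
    stop(sprintf("cell '%s' never observed in embryo '%s'",
                 cell, embryoId(table)))
  if (kind == "birth") min(times) else max(times)
}

#' Align embryo time axes on a shared developmental event
#'
#' Shifts each table's time column so the event occurs at time 0 (times
#' before the event become negative). Within-embryo time differences are
#' preserved exactly; the resulting tables carry \code{timeUnits =
#' "aligned"}. Aligning already-aligned tables is idempotent (all offsets
#' 0). Embryo ids must be unique across the input.
#'
#' @param tables list of \linkS4class{EmbryoTable}s sharing one time-units
#'   flag.
#' @param cell event cell name, observed in every embryo.
#' @param kind \code{"birth"} or \code{"last"}.
#' @return list with elements \code{tables} (aligned) and
#'   \code{alignment} (a \linkS4class{TimeAlignment}; offsets are the
#'   amounts added to each embryo's times).
#' @export
alignTimes <- function(tables, cell, kind = c("birth", "last")) {
  if (is(tables, "EmbryoTable")) tables <- list(tables)
  kind <- match.arg(kind)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "EmbryoTable")))
  tu <- unique(vapply(tables, timeUnits, character(1)))
  if (length(tu) > 1L)
    stop(sprintf("mixed time units across embryos: %s",
                 paste(tu, collapse = ", ")))
  ids <- vapply(tables, embryoId, character(1))
  if (anyDuplicated(ids))
    stop("embryo ids must be unique across the tables being aligned")
  ev <- vapply(tables, function(tb) {
    tryCatch(eventTime(tb, cell, kind), error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(ev))
    stop(sprintf("event cell '%s' not observed in embryo(s): %s",
                 cell, paste(ids[is.na(ev)], collapse = ", ")))
  offsets <- stats::setNames(-ev, ids)
  aligned <- mapply(function(tb, off) {
    d <- cdData(tb)
    d$time <- d$time + off
    tb@timeUnits <- "aligned"
    setEmbryoData(tb, d)
  }, tables, offsets, SIMPLIFY = FALSE)
  names(aligned) <- ids
  list(tables = aligned,
       alignment = new("TimeAlignment", eventCell = cell, eventKind = kind,
                       offsets = offsets))
}
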