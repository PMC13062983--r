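## Per-cell and per-lineage expression summaries for coloring and for
## cross-embryo trajectory comparison.

#' Mean expression per cell
#'
#' Arithmetic mean of each cell's values over every timepoint at which a
#' value exists; cells with no recorded value are omitted.
#'
#' @param table an \linkS4class{EmbryoTable}.
#' @param exprColumn expression column (default \code{"blot"}).
#' @return named numeric vector, one entry per expressing cell.
#' @export
cellMeanExpression <- function(table, exprColumn = "blot") {
  stopifnot(is(table, "EmbryoTable"))
  d <- cdData(table)
  if (!(exprColumn %in% names(d)))
    stop(sprintf("expression column '%s' absent from embryo '%s'",
                 exprColumn, embryoId(table)))
  keep <- !is.na(d[[exprColumn]])
  if (!any(keep)) return(stats::setNames(numeric(), character()))
  vapply(split(d[[exprColumn]][keep], d$cell[keep]), mean, numeric(1))
}

#' Per-lineage expression trajectories across embryos
#'
#' For each embryo and each timepoint, the mean expression over the cells
#' selected by the given Sulston patterns (with descendants by default,
#' matching selections like "ABalp and its descendants") that are present
#' at that timepoint. Timepoints with no selected cell are omitted, never
#' interpolated. Tables should already be time-aligned
#' (\code{\link{alignTimes}}); a warning is raised when the time axes look
#' unaligned (no negative times and mismatched start times).
#'
#' @param tables list of \linkS4class{EmbryoTable}s (or one table).
#' @param patterns Sulston patterns selecting the lineage(s).
#' @param includeDescendants include observed descendants of matches
#'   (default TRUE).
#' @param exprColumn expression column (default \code{"blot"}).
#' @param conditions optional character vector (recycled) labelling each
#'   embryo's condition; defaults to the embryo id.
#' @return data.frame with columns \code{embryo_id}, \code{condition},
#'   \code{time}, \code{mean_expr}, \code{n_cells}; times strictly
#'   increasing within each embryo.
#' @export
lineageTrajectory <- function(tables, patterns, includeDescendants = TRUE,
                              exprColumn = "blot", conditions = NULL) {
  if (is(tables, "EmbryoTable")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "EmbryoTable")))
  ids <- vapply(tables, embryoId, character(1))
  if (is.null(conditions)) conditions <- ids
  conditions <- rep_len(as.character(conditions), length(tables))
  if (length(tables) > 1L) {
    mins <- vapply(tables, function(tb) min(cdData(tb)$time), numeric(1))
    if (all(mins > 0) && length(unique(mins)) > 1L)
      warning("time axes look unaligned (no negative times, mismatched starts); consider alignTimes()")
  }
  out <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    d <- cdData(tb)
    if (!(exprColumn %in% names(d)))
      stop(sprintf("expression column '%s' absent from embryo '%s'",
                   exprColumn, ids[i]))
    sel <- selectCells(tb, patterns, includeDescendants = includeDescendants)
    keep <- d$cell %in% sel & !is.na(d[[exprColumn]])
    if (!any(keep))
      stop(sprintf("selection matches no expressing cells in embryo '%s'",
                   ids[i]))
    sub <- d[keep, , drop = FALSE]
    agg <- vapply(split(sub[[exprColumn]], sub$time),
                  function(v) c(mean(v), length(v)), numeric(2))
    tt <- as.numeric(colnames(agg))
    ord <- order(tt)
    out[[i]] <- data.frame(embryo_id = unname(ids[i]),
                           condition = unname(conditions[i]),
                           time = tt[ord], mean_expr = unname(agg[1L, ord]),
                           n_cells = as.integer(agg[2L, ord]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subset several embryos at once
#'
#' Restricts each table to the cells selected by the given patterns and/or
#' to a time window. Empty results are allowed (with a warning), so batch
#' runs continue past embryos not covering the window.
#'
#' @param tables list of \linkS4class{EmbryoTable}s (or one table).
#' @param patterns optional Sulston patterns; NULL keeps all cells.
#' @param includeDescendants include observed descendants of matches
#'   (default TRUE).
#' @param timeWindow optional length-2 numeric [start, end]; NULL keeps
#'   all timepoints.
#' @return list of subsetted \linkS4class{EmbryoTable}s (a single input
#'   table returns a single table).
#' @export
subsetEmbryos <- function(tables, patterns = NULL, includeDescendants = TRUE,
                          timeWindow = NULL) {
  single <- is(tables, "EmbryoTable")
  if (single) tables <- list(tables)
  stopifnot(all(vapply(tables, is, logical(1), "EmbryoTable")))
  if (!is.null(timeWindow)) stopifnot(length(timeWindow) == 2L)
  out <- lapply(tables, function(tb) {
    d <- cdData(tb)
    keep <- rep(TRUE, nrow(d))
    if (!is.null(patterns)) {
      sel <- suppressWarnings(
        selectCells(tb, patterns, includeDescendants = includeDescendants))
      keep <- keep & d$cell %in% sel
    }
    if (!is.null(timeWindow))
      keep <- keep & d$time >= timeWindow[1L] & d$time <= timeWindow[2L]
    if (!any(keep))
      warning(sprintf("subset of embryo '%s' is empty", embryoId(tb)))
    setEmbryoData(tb, d[keep, , drop = FALSE])
  })
  if (single) out[[1L]] else out
}
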