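## Rendering: 3D nuclear-position plots (orthographic projection via
## ggplot2), lineage trees colored by expression (SVG written directly),
## and static figure export.

#' Plot styling options
#'
#' @param colorColumn column mapped to marker color, or a constant color
#'   string (e.g. \code{"grey30"}) when no such column exists.
#' @param colorMin,colorMax optional clamp range: values outside render at
#'   the range endpoints, never overflow the scale.
#' @param highlight list of \code{list(pattern=, shape=, color=)} entries;
#'   cells matching each Sulston pattern (with descendants) are drawn on
#'   top with the given marker shape and color.
#' @param markerSizeMode \code{"constant"} or \code{"diameter"} (scale
#'   markers by the \code{diameter} column when present).
#' @return a StyleSpec list.
#' @export
styleSpec <- function(colorColumn = "blot", colorMin = NULL,
                      colorMax = NULL, highlight = list(),
                      markerSizeMode = c("constant", "diameter")) {
  markerSizeMode <- match.arg(markerSizeMode)
  if (!is.null(colorMin) && !is.null(colorMax) && !(colorMin < colorMax))
    stop("colorMin must be < colorMax")
  for (h in highlight)
    if (!all(c("pattern", "shape", "color") %in% names(h)))
      stop("each highlight needs 'pattern', 'shape' and 'color'")
  structure(list(colorColumn = colorColumn, colorMin = colorMin,
                 colorMax = colorMax, highlight = highlight,
                 markerSizeMode = markerSizeMode),
            class = "StyleSpec")
}

# orthographic projection matrix for a view direction given by azimuth
# (about +z) then elevation (toward the viewer); rows 1-2 give the screen
# axes, row 3 the depth
.viewMatrix <- function(azimuth, elevation) {
  az <- azimuth * pi / 180; el <- elevation * pi / 180
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(el), sin(el), 0, -sin(el), cos(el)), 3, 3)
  Rx %*% Rz
}

.clamp <- function(v, lo, hi) {
  if (!is.null(lo)) v <- pmax(v, lo)
  if (!is.null(hi)) v <- pmin(v, hi)
  v
}

#' 3D nuclear-position plot at one timepoint
#'
#' Draws one marker per cell present at the requested time, as an
#' orthographic projection onto the screen plane with equal aspect ratio
#' (axes in the table's units, as labelled). Marker color comes from the
#' style's color column, clamped to [colorMin, colorMax]; missing values
#' render grey. Highlighted selections are drawn on top with their own
#' shapes and colors.
#'
#' @param table an \linkS4class{EmbryoTable}.
#' @param time a timepoint present in the table.
#' @param style a \code{\link{styleSpec}}.
#' @param azimuth,elevation view angles in degrees; the defaults
#'   (0, 90) look down the z axis, i.e. the dorsal aspect of a
#'   canonically rotated embryo.
#' @return a ggplot object (print it, or pass to
#'   \code{\link{exportFigure}}).
#' @export
plotEmbryo3D <- function(table, time, style = styleSpec(),
                         azimuth = 0, elevation = 90) {
  stopifnot(is(table, "EmbryoTable"), inherits(style, "StyleSpec"))
  d <- cdData(table)
  d <- d[d$time == time, , drop = FALSE]
  if (!nrow(d))
    stop(sprintf("time %g not present in embryo '%s'",
                 time, embryoId(table)))
  V <- .viewMatrix(azimuth, elevation)
  scr <- as.matrix(d[, c("x", "y", "z")]) %*% t(V)
  pd <- data.frame(cell = d$cell, sx = scr[, 1L], sy = scr[, 2L],
                   depth = scr[, 3L], stringsAsFactors = FALSE)
  has_col <- style$colorColumn %in% names(d)
  if (has_col)
    pd$value <- .clamp(d[[style$colorColumn]], style$colorMin,
                       style$colorMax)
  if (style$markerSizeMode == "diameter" && "diameter" %in% names(d)) {
    pd$size <- d$diameter
  } else pd$size <- NA_real_
  unit_lab <- sprintf("(%s units)", coordUnits(table))
  p <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$sx, y = .data$sy))
  if (has_col) {
    lims <- c(if (is.null(style$colorMin)) min(pd$value, na.rm = TRUE)
              else style$colorMin,
              if (is.null(style$colorMax)) max(pd$value, na.rm = TRUE)
              else style$colorMax)
    if (lims[1L] == lims[2L]) lims <- lims + c(-0.5, 0.5)
    p <- p +
      ggplot2::geom_point(ggplot2::aes(color = .data$value), size = 3) +
      ggplot2::scale_color_gradientn(
        colors = grDevices::hcl.colors(64, "viridis"),
        limits = lims, na.value = "grey70", name = style$colorColumn)
  } else {
    const <- if (is.character(style$colorColumn) &&
                 !nzchar(style$colorColumn)) "grey30" else style$colorColumn
    if (!is.character(const)) const <- "grey30"
    p <- p + ggplot2::geom_point(color = const, size = 3)
  }
  for (h in style$highlight) {
    sel <- suppressWarnings(
      selectCells(pd$cell, h$pattern, includeDescendants = TRUE))
    hp <- pd[pd$cell %in% sel, , drop = FALSE]
    if (nrow(hp))
      p <- p + ggplot2::geom_point(data = hp, shape = h$shape,
                                   color = h$color, size = 4)
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(x = paste("screen x", unit_lab),
                  y = paste("screen y", unit_lab),
                  title = sprintf("%s, t = %g", embryoId(table), time)) +
    ggplot2::theme_minimal()
}

#' Lay out a lineage tree for plotting
#'
#' Builds the chart geometry for the given root and all its observed
#' descendants inside [tStart, tEnd]: leaves (cells with no observed
#' daughter in the window) get consecutive x positions in canonical
#' sibling order (a<p, d<v, l<r), each internal cell sits at the midpoint
#' of its daughters, and every cell spans [first, last observation] in the
#' window vertically.
#'
#' @param table an \linkS4class{EmbryoTable}.
#' @param root root cell name (Sulston).
#' @param tStart,tEnd time window; defaults cover the whole table.
#' @return a \linkS4class{TreeLayout}.
#' @seealso \code{\link{renderTree}}
#' @export
buildTreeLayout <- function(table, root, tStart = NULL, tEnd = NULL) {
  stopifnot(is(table, "EmbryoTable"), length(root) == 1L)
  if (!isLineageName(root))
    stop(sprintf("root '%s' is not a parseable Sulston name", root))
  d <- cdData(table)
  if (is.null(tStart)) tStart <- min(d$time)
  if (is.null(tEnd)) tEnd <- max(d$time)
  d <- d[d$time >= tStart & d$time <= tEnd, , drop = FALSE]
  obs <- unique(d$cell)
  member <- obs[suppressWarnings(isDescendant(obs, root, inclusive = TRUE))]
  if (!length(member))
    stop(sprintf("root '%s' (or any descendant) never observed in window [%g, %g]",
                 root, tStart, tEnd))
  sub <- d[d$cell %in% member, , drop = FALSE]
  birth <- vapply(split(sub$time, sub$cell), min, numeric(1))
  end <- vapply(split(sub$time, sub$cell), max, numeric(1))
  cells <- names(birth)
  parent <- vapply(cells, function(cl) {
    p <- suppressWarnings(parentOf(cl))
    while (!is.na(p) && !(p %in% cells)) {
      if (identical(p, root)) break
      p <- suppressWarnings(parentOf(p))
    }
    if (!is.na(p) && p %in% cells) p else NA_character_
  }, character(1))
  kids_of <- split(cells[!is.na(parent)], parent[!is.na(parent)])
  roots <- cells[is.na(parent)]
  # depth-first leaf ordering in canonical sibling order
  x <- stats::setNames(rep(NA_real_, length(cells)), cells)
  leaf_ctr <- 0
  assign_x <- function(cl) {
    kids <- kids_of[[cl]]
    if (is.null(kids) || !length(kids)) {
      leaf_ctr <<- leaf_ctr + 1
      x[cl] <<- leaf_ctr
    } else {
      for (k in orderSiblings(kids)) assign_x(k)
      x[cl] <<- mean(x[kids])
    }
    invisible(NULL)
  }
  for (r in orderSiblings(roots)) assign_x(r)
  layout <- data.frame(cell = cells, x = unname(x[cells]),
                       birth = unname(birth), end = unname(end),
                       parent = unname(parent),
                       leaf = !(cells %in% names(kids_of)),
                       stringsAsFactors = FALSE)
  layout <- layout[order(layout$x), , drop = FALSE]
  rownames(layout) <- NULL
  new("TreeLayout", cells = layout, root = root,
      window = as.numeric(c(tStart, tEnd)))
}

# map values to hex colors over a clamp range; NA -> grey
.colorsFor <- function(values, lo, hi, palette = "viridis") {
  pal <- grDevices::hcl.colors(256, palette)
  if (is.null(lo)) lo <- suppressWarnings(min(values, na.rm = TRUE))
  if (is.null(hi)) hi <- suppressWarnings(max(values, na.rm = TRUE))
  if (!is.finite(lo) || !is.finite(hi)) return(rep("#BBBBBB", length(values)))
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  v <- .clamp(values, lo, hi)
  idx <- 1L + as.integer(round((v - lo) / (hi - lo) * 255))
  out <- pal[idx]
  out[is.na(values)] <- "#BBBBBB"
  out
}

#' Render a lineage tree as an SVG vector graphic
#'
#' Time runs downward. Each (cell, time) observation in the window becomes
#' one colored vertical sub-segment of that cell's branch (class
#' \code{"seg"} in the SVG), colored by the expression column with
#' clamping to the style's range; horizontal connectors (class
#' \code{"join"}) join each parent to its daughters at the division time.
#' If the expression column is absent the tree is drawn monochrome with a
#' warning.
#'
#' @param layout a \linkS4class{TreeLayout} built from the same table.
#' @param table the \linkS4class{EmbryoTable} supplying expression values.
#' @param exprColumn expression column (default \code{"blot"}).
#' @param style a \code{\link{styleSpec}} (clamp range is honoured).
#' @param path output path for the .svg file.
#' @param leafSpacing,timeScale pixels per leaf and per time unit.
#' @return invisibly, \code{path}.
#' @export
renderTree <- function(layout, table, exprColumn = "blot",
                       style = styleSpec(), path,
                       leafSpacing = 28, timeScale = 14) {
  stopifnot(is(layout, "TreeLayout"), is(table, "EmbryoTable"))
  lay <- layout@cells
  d <- cdData(table)
  d <- d[d$cell %in% lay$cell &
           d$time >= layout@window[1L] & d$time <= layout@window[2L], ,
         drop = FALSE]
  mono <- !(exprColumn %in% names(d))
  if (mono)
    warning(sprintf(
      "expression column '%s' absent; rendering a monochrome tree",
      exprColumn))
  margin <- 30
  X <- function(x) margin + (x - min(lay$x)) * leafSpacing
  Y <- function(t) margin + (t - layout@window[1L]) * timeScale
  width <- ceiling(X(max(lay$x)) + margin)
  height <- ceiling(Y(layout@window[2L] + 1) + margin)
  segs <- character(0)
  d <- d[order(d$cell, d$time), , drop = FALSE]
  values <- if (mono) rep(NA_real_, nrow(d)) else d[[exprColumn]]
  cols <- if (mono) rep("#555555", nrow(d)) else
    .colorsFor(values, style$colorMin, style$colorMax)
  by_cell <- split(seq_len(nrow(d)), d$cell)
  # one colored sub-segment per (cell, time) row: from that observation
  # down to the next one (or one median step for the last)
  step_all <- stats::median(diff(sort(unique(d$time))))
  if (!is.finite(step_all) || step_all <= 0) step_all <- 1
  for (cl in names(by_cell)) {
    idx <- by_cell[[cl]]
    tt <- d$time[idx]
    xx <- X(lay$x[match(cl, lay$cell)])
    t_next <- c(tt[-1L], tt[length(tt)] + step_all)
    for (j in seq_along(idx)) {
      segs <- c(segs, sprintf(
        '<line class="seg" x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="4"><title>%s t=%g</title></line>',
        xx, Y(tt[j]), xx, Y(t_next[j]), cols[idx[j]],
        .xmlEscape(cl), tt[j]))
    }
  }
  joins <- character(0)
  for (i in seq_len(nrow(lay))) {
    p <- lay$parent[i]
    if (is.na(p)) next
    pi_ <- match(p, lay$cell)
    yy <- Y(lay$birth[i])
    joins <- c(joins, sprintf(
      '<line class="join" x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#888888" stroke-width="2"/>',
      X(lay$x[pi_]), yy, X(lay$x[i]), yy))
  }
  svg <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<title>Lineage tree rooted at %s</title>',
            .xmlEscape(layout@root)),
    '<rect width="100%" height="100%" fill="white"/>',
    joins, segs,
    vapply(which(lay$leaf), function(i) sprintf(
      '<text x="%.2f" y="%.2f" font-size="9" text-anchor="middle">%s</text>',
      X(lay$x[i]), Y(lay$end[i] + 1) + 10, .xmlEscape(lay$cell[i])),
      character(1)),
    '</svg>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(svg, con, sep = "\n")
  invisible(path)
}

.xmlEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Plot cross-embryo expression trajectories
#'
#' One line per embryo (colored by condition) of mean lineage expression
#' versus aligned time, as returned by \code{\link{lineageTrajectory}}.
#' Gaps in a trajectory are shown as gaps, never interpolated.
#'
#' @param traj data.frame from \code{\link{lineageTrajectory}}.
#' @return a ggplot object.
#' @export
plotTrajectory <- function(traj) {
  stopifnot(all(c("embryo_id", "condition", "time", "mean_expr") %in%
                  names(traj)))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$mean_expr,
                                     group = .data$embryo_id,
                                     color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "aligned time", y = "mean lineage expression") +
    ggplot2::theme_minimal()
}

#' Export a figure to a static image file
#'
#' Writes a ggplot figure to PNG, SVG or PDF with the requested size.
#' Re-exporting the same figure yields identical image dimensions.
#'
#' @param figure a ggplot object.
#' @param path output path.
#' @param format \code{"png"}, \code{"svg"} or \code{"pdf"}; default
#'   inferred from the path's extension.
#' @param width,height size in inches.
#' @param dpi resolution for PNG.
#' @return invisibly, \code{path}.
#' @export
exportFigure <- function(figure, path, format = NULL, width = 7,
                         height = 5, dpi = 150) {
  if (is.null(format)) format <- tolower(sub("^.*\\.", "", path))
  if (!format %in% c("png", "svg", "pdf"))
    stop(sprintf("unsupported figure format: '%s'", format))
  switch(format,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = dpi, type = "cairo"),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height))
  on.exit(grDevices::dev.off())
  print(figure)
  invisible(path)
}
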