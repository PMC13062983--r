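# 3D plots, tree layout/rendering, figure export

test_that("plot3d draws one marker per cell with clamped colors", {
  d <- data.frame(cell = c("ABa", "ABp", "EMS", "P2"), time = 4,
                  x = c(0, 10, 5, 15), y = c(0, 2, 8, 4),
                  z = c(1, 2, 3, 4), blot = c(10, 50, 9000, 30))
  tb <- EmbryoTable(d, coordUnits = "micron")
  st <- styleSpec(colorMin = 0, colorMax = 100)
  p <- plotEmbryo3D(tb, 4, st)
  ld <- ggplot2::layer_data(p, 1L)
  expect_equal(nrow(ld), 4L)            # marker count == cells at time
  # a value above colorMax renders at the max color (clamped in data)
  expect_equal(max(p$data$value), 100)
  expect_error(plotEmbryo3D(tb, 99), "99")
  expect_error(styleSpec(colorMin = 5, colorMax = 5), "colorMin")

  # highlighted markers are exactly the selectCells() result
  sim <- simulateEmbryo(seed = 5)
  st2 <- styleSpec(highlight = list(list(pattern = "Cxp", shape = 17,
                                         color = "red")))
  p2 <- plotEmbryo3D(sim$table, 20, st2)
  hl <- ggplot2::layer_data(p2, 2L)
  want <- selectCells(
    cdData(sim$table)$cell[cdData(sim$table)$time == 20], "Cxp",
    includeDescendants = TRUE)
  expect_equal(nrow(hl), length(want))
})

test_that("tree layout obeys midpoint and sibling-interval invariants", {
  # single cell, no divisions: one vertical segment
  d1 <- data.frame(cell = "MSa", time = 3:6, x = 0, y = 0, z = 0)
  lay1 <- buildTreeLayout(EmbryoTable(d1), "MSa")
  expect_equal(nrow(treeCells(lay1)), 1L)
  expect_equal(treeCells(lay1)$birth, 3)
  expect_equal(treeCells(lay1)$end, 6)

  # root with two daughters: parent at the midpoint
  d2 <- rbind(data.frame(cell = "Ca", time = 1:2, x = 0, y = 0, z = 0),
              data.frame(cell = c("Caa", "Cap"), time = 3, x = 0, y = 0,
                         z = 0))
  lay2 <- buildTreeLayout(EmbryoTable(d2), "Ca")
  lc <- treeCells(lay2)
  expect_equal(nrow(lc), 3L)
  expect_equal(lc$x[lc$cell == "Ca"],
               mean(lc$x[lc$cell %in% c("Caa", "Cap")]))
  # canonical sibling order: a before p
  expect_lt(lc$x[lc$cell == "Caa"], lc$x[lc$cell == "Cap"])

  expect_error(buildTreeLayout(EmbryoTable(d2), "MSa"), "never observed")

  # invariants on random lineages to depth 10
  for (seed in 61:64) {
    tb <- randomLineageTable(seed, depth = 10)
    lay <- treeCells(buildTreeLayout(tb, "C"))
    d <- cdData(tb)
    # leaf count equals cells with no observed daughters
    obs <- unique(d$cell)
    nkids <- vapply(obs, function(cl)
      length(daughtersOf(cl, observed = obs)), integer(1))
    expect_equal(sum(lay$leaf), sum(nkids == 0))
    # parents at daughter midpoints; sibling subtrees on disjoint x ranges
    for (p in unique(na.omit(lay$parent))) {
      kids <- lay$cell[!is.na(lay$parent) & lay$parent == p]
      expect_equal(lay$x[lay$cell == p], mean(lay$x[lay$cell %in% kids]))
      if (length(kids) == 2) {
        # descendant = string prefix for these single-founder suffix trees
        span <- function(cl) range(lay$x[startsWith(lay$cell, cl)])
        s1 <- span(kids[1]); s2 <- span(kids[2])
        expect_true(s1[2] < s2[1] || s2[2] < s1[1])
      }
      # parent/daughter vertical spans meet at the division
      for (k in kids)
        expect_equal(lay$birth[lay$cell == k],
                     lay$end[lay$cell == p] + 1)
    }
  }
})

test_that("renderTree writes well-formed SVG with one segment per row", {
  skip_if_not_installed("xml2")
  tb <- randomLineageTable(65, depth = 5)
  lay <- buildTreeLayout(tb, "C", tStart = 2, tEnd = 12)
  f <- tempfile(fileext = ".svg")
  renderTree(lay, tb, path = f)
  doc <- xml2::read_xml(f)   # parses => well-formed
  svgtxt <- readLines(f)
  nseg <- sum(lengths(regmatches(svgtxt, gregexpr('class="seg"', svgtxt))))
  d <- cdData(tb)
  inwin <- d$cell %in% treeCells(lay)$cell & d$time >= 2 & d$time <= 12
  expect_equal(nseg, sum(inwin))

  # all-equal expression renders in a single color
  d2 <- d; d2$blot <- 5
  tb2 <- EmbryoTable(d2, coordUnits = "micron")
  f2 <- tempfile(fileext = ".svg")
  renderTree(buildTreeLayout(tb2, "C", 2, 12), tb2, path = f2)
  cols <- unique(unlist(regmatches(readLines(f2),
                                   gregexpr('class="seg"[^/]*stroke="([^"]+)"',
                                            readLines(f2)))))
  strokes <- unique(sub('.*stroke="([^"]+)".*', "\\1", cols))
  expect_length(strokes, 1L)

  # absent expression column: monochrome with a warning
  expect_warning(renderTree(lay, tb, exprColumn = "nope",
                            path = tempfile(fileext = ".svg")),
                 "monochrome")
})

test_that("exportFigure writes the declared formats deterministically", {
  p <- plotTrajectory(data.frame(embryo_id = "a", condition = "wt",
                                 time = 1:5, mean_expr = (1:5)^2,
                                 n_cells = 1L))
  png1 <- tempfile(fileext = ".png")
  exportFigure(p, png1, width = 4, height = 3, dpi = 96)
  expect_identical(readBin(png1, "raw", 8L),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a,
                            0x0a)))
  png2 <- tempfile(fileext = ".png")
  exportFigure(p, png2, width = 4, height = 3, dpi = 96)
  dims <- function(f) {
    r <- readBin(f, "raw", 33L)
    list(w = sum(as.integer(r[17:20]) * 256^(3:0)),
         h = sum(as.integer(r[21:24]) * 256^(3:0)))
  }
  expect_identical(dims(png1), dims(png2))
  expect_equal(dims(png1)$w, 4 * 96)

  svgf <- tempfile(fileext = ".svg")
  exportFigure(p, svgf)
  expect_gt(file.size(svgf), 0)
  pdff <- tempfile(fileext = ".pdf")
  exportFigure(p, pdff, format = "pdf")
  expect_identical(rawToChar(readBin(pdff, "raw", 4L)), "%PDF")
  expect_error(exportFigure(p, tempfile(fileext = ".bmp")), "unsupported")

  # batch export: N systematic files
  outdir <- tempfile(); dir.create(outdir)
  for (i in 1:3)
    exportFigure(p, file.path(outdir, sprintf("emb%02d_traj.png", i)),
                 width = 2, height = 2)
  expect_length(list.files(outdir, pattern = "^emb\\d+_traj\\.png$"), 3L)
})
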