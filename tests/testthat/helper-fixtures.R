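# Fixture builders shared across the suite. Everything is generated in
# code; no binary files ship with the package.

DIV_LETTERS <- c("a", "p", "l", "r", "d", "v")
LETTER_FOUNDERS <- c("AB", "MS", "E", "C", "D")

# random valid EmbryoTable with expression columns and some missing values
randomEmbryoTable <- function(seed, nCells = 12, nTimes = 6,
                              withGfp = FALSE, literals = TRUE) {
  set.seed(seed)
  suffixes <- vapply(seq_len(nCells), function(i)
    paste(sample(DIV_LETTERS, sample(0:4, 1), replace = TRUE),
          collapse = ""), character(1))
  cells <- unique(paste0(sample(LETTER_FOUNDERS, nCells, TRUE), suffixes))
  if (literals) cells <- unique(c(cells, "Nuc101", "polar body"))
  grid <- expand.grid(cell = cells, time = seq_len(nTimes),
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < 0.8
  keep[1L] <- TRUE
  d <- grid[keep, , drop = FALSE]
  n <- nrow(d)
  d$x <- round(runif(n, 0, 512), 3)
  d$y <- round(runif(n, 0, 512), 3)
  d$z <- round(runif(n, 0, 30), 3)
  d$blot <- round(runif(n, 0, 5000), 2)
  d$blot[runif(n) < 0.15] <- NA
  if (withGfp) d$gfp <- round(rexp(n, 1 / 100), 2)
  EmbryoTable(d, embryoId = sprintf("rand%d", seed))
}

# build a StarryNite-style zip: one nuclei file per timepoint, records are
# index,valid,pred,succ1,succ2,x,y,z,diameter,name,expr
makeStarryNiteZip <- function(zipPath, timepoints) {
  dir <- tempfile("snsrc")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  files <- character()
  for (tp in names(timepoints)) {
    f <- file.path(dir, sprintf("t%s-nuclei", tp))
    writeLines(timepoints[[tp]], f)
    files <- c(files, f)
  }
  out <- system2("python", c("-m", "zipfile", "-c", shQuote(zipPath),
                             shQuote(files)),
                 stdout = TRUE, stderr = TRUE)
  stopifnot(file.exists(zipPath))
  zipPath
}

nucleusLine <- function(idx, valid, x, y, z, name, expr, diam = 4) {
  sprintf("%d,%d,-1,-1,-1,%g,%g,%g,%g,%s,%g", idx, valid, x, y, z, diam,
          name, expr)
}

# toy canonical embryo whose point cloud is exactly axis-aligned: bulk
# cells come in 4-fold (y,z)-mirrored sets so all covariance cross-terms
# vanish and the first principal axis is exactly x
rollConfigTable <- function(groupAngles, r = 5) {
  rows <- list()
  add <- function(cell, x, y, z)
    rows[[length(rows) + 1L]] <<- data.frame(cell = cell, time = 1,
                                             x = x, y = y, z = z,
                                             stringsAsFactors = FALSE)
  k <- 0
  for (sx in c(-10, 10)) for (sy in c(-1, 1)) for (sz in c(-0.5, 0.5)) {
    k <- k + 1
    add(sprintf("bulk%d", k), sx, sy, sz)
  }
  add("Cap", -12, 0, 0)   # posterior, on-axis
  groupCell <- c(dorsal = "Caaa", left = "MSpp", right = "MSap")
  for (g in names(groupAngles)) {
    a <- groupAngles[[g]]
    y <- r * cos(a); z <- r * sin(a)
    add(groupCell[[g]], 0, y, z)
    k <- k + 1; add(sprintf("cw%da", k), 0, -y, z)
    add(sprintf("cw%db", k), 0, y, -z)
    add(sprintf("cw%dc", k), 0, -y, -z)
  }
  EmbryoTable(do.call(rbind, rows), embryoId = "roll",
              coordUnits = "micron")
}

rollGroupsFor <- function(groupAngles) {
  pats <- c(dorsal = "Cxaa", left = "MSpp", right = "MSap")
  args <- list(posterior = "Cxp", dorsal = NULL, left = NULL, right = NULL)
  for (g in names(groupAngles)) args[[g]] <- unname(pats[[g]])
  do.call(landmarkGroups, args)
}

wrapAngle <- function(a) atan2(sin(a), cos(a))

# extract the fitted roll: for rollConfigTable the long axis is exactly x,
# so the fitted rotation is a pure roll about x
fittedRoll <- function(tf) atan2(tf@rotation[3, 2], tf@rotation[2, 2])

# brute-force grid minimiser of summed squared (wrapped) angular deviation
gridRoll <- function(candidates, step = 0.001) {
  grid <- seq(-pi, pi, by = step)
  obj <- vapply(grid, function(th)
    sum(wrapAngle(candidates - th)^2), numeric(1))
  grid[which.min(obj)]
}

# random lineage table: a binary tree of divisions under one founder, one
# row per (cell, time) from birth to division/tEnd
randomLineageTable <- function(seed, founder = "C", depth = 6,
                               divEvery = 2) {
  set.seed(seed)
  rows <- list()
  grow <- function(cell, birth, gen) {
    divide <- gen < depth && runif(1) < 0.85
    end <- if (divide) birth + divEvery else birth + divEvery + 1
    for (t in birth:end)
      rows[[length(rows) + 1L]] <<- data.frame(
        cell = cell, time = t, x = runif(1), y = runif(1), z = runif(1),
        blot = runif(1, 0, 100), stringsAsFactors = FALSE)
    if (divide) {
      axis <- sample(c("ap", "lr", "dv"), 1)
      for (l in strsplit(axis, "")[[1L]])
        grow(paste0(cell, l), end + 1, gen + 1)
    }
  }
  grow(founder, 1, 0)
  EmbryoTable(do.call(rbind, rows), embryoId = sprintf("lin%d", seed),
              coordUnits = "micron")
}

# spec'd depth cohort: nEmb embryos x nCells cells, z uniform on [0, 30],
# E = scale_i * exp(-k z) * lognormal(sigma)
depthCohort <- function(seed, k = 0.04, nEmb = 5, nCells = 200,
                        sigma = 0.1, zMax = 30) {
  set.seed(seed)
  lapply(seq_len(nEmb), function(i) {
    z <- runif(nCells, 0, zMax)
    scale_i <- exp(runif(1, 4, 6))
    d <- data.frame(cell = sprintf("Nuc%d", seq_len(nCells)),
                    time = 1, x = runif(nCells, 0, 50),
                    y = runif(nCells, 0, 30), z = z,
                    blot = scale_i * exp(-k * z) *
                      exp(rnorm(nCells, 0, sigma)),
                    stringsAsFactors = FALSE)
    EmbryoTable(d, embryoId = sprintf("emb%d", i), coordUnits = "micron")
  })
}

expect_tables_equal <- function(a, b, tol = 1e-6) {
  da <- cdData(a); db <- cdData(b)
  expect_identical(names(da), names(db))
  expect_identical(nrow(da), nrow(db))
  expect_identical(da$cell, db$cell)
  for (col in setdiff(names(da), "cell"))
    expect_equal(da[[col]], db[[col]], tolerance = tol)
}
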