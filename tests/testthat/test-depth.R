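# Exponential depth-attenuation model: fitting, correction, serialization

test_that("a noise-free exponential profile is fitted exactly", {
  z <- seq(0, 30, length.out = 40)
  d <- data.frame(cell = sprintf("n%d", seq_along(z)), time = 1,
                  x = 0, y = 0, z = z, blot = 100 * exp(-0.05 * z))
  tb <- EmbryoTable(d, coordUnits = "micron")
  m <- suppressWarnings(fitDepthModel(tb))
  expect_equal(decayRate(m), 0.05, tolerance = 1e-9)
  expect_equal(unname(m@scales), log(100), tolerance = 1e-9)

  # constant expression over any depth range gives k = 0
  d$blot <- 500
  m0 <- suppressWarnings(fitDepthModel(EmbryoTable(d, coordUnits = "micron")))
  expect_equal(decayRate(m0), 0, tolerance = 1e-9)
})

test_that("fitting validates inputs and warns on single embryos", {
  d <- data.frame(cell = sprintf("n%d", 1:12), time = 1, x = 0, y = 0,
                  z = 1:12, blot = exp(-(1:12) * 0.1))
  tb <- EmbryoTable(d, coordUnits = "micron")
  expect_warning(fitDepthModel(tb), "single embryo")
  expect_error(suppressWarnings(
    fitDepthModel(EmbryoTable(d), exprColumn = "blot")), "micron")
  expect_error(suppressWarnings(fitDepthModel(tb, exprColumn = "gfp")),
               "gfp")
  few <- EmbryoTable(d[1:5, ], coordUnits = "micron")
  expect_error(suppressWarnings(fitDepthModel(few)), ">= 10")
  flat <- d; flat$z <- 7
  expect_error(suppressWarnings(
    fitDepthModel(EmbryoTable(flat, coordUnits = "micron"))),
    "no depth range")
})

test_that("shared slope is recovered across replicates and is invariant
          to relabeling and row order", {
  tabs <- depthCohort(1)
  m <- fitDepthModel(tabs)
  expect_lt(abs(decayRate(m) - 0.04) / 0.04, 0.10)
  expect_equal(sort(names(m@scales)), sprintf("emb%d", 1:5))

  # permute rows and relabel embryos: identical slope
  tabs2 <- lapply(seq_along(tabs), function(i) {
    d <- cdData(tabs[[i]])
    set.seed(i)
    EmbryoTable(d[sample(nrow(d)), ], embryoId = sprintf("other%d", i),
                coordUnits = "micron")
  })
  expect_equal(decayRate(fitDepthModel(tabs2)), decayRate(m),
               tolerance = 1e-12)
})

test_that("correction boosts with depth and is anchored at zRef", {
  tabs <- depthCohort(2)
  m <- fitDepthModel(tabs, zRef = 10)
  tb <- tabs[[1L]]
  corr <- applyDepthModel(tb, m)
  d0 <- cdData(tb); d1 <- cdData(corr)
  expect_identical(d1$blot_raw, d0$blot)        # original preserved
  expect_identical(d1$x, d0$x)                  # positions untouched
  # monotone increasing factor in z for k > 0
  fac <- d1$blot / d1$blot_raw
  expect_true(all(diff(fac[order(d1$z)]) >= -1e-12))
  # a point exactly at zRef is a fixed point
  dd <- d0[1:12, ]; dd$z <- 10; dd$cell <- sprintf("w%d", 1:12)
  at_ref <- applyDepthModel(EmbryoTable(dd, coordUnits = "micron"), m)
  expect_equal(cdData(at_ref)$blot, dd$blot, tolerance = 1e-12)

  # k = 0 model is the identity
  m0 <- new("DepthModel", decayRate = 0, scales = c(e = 1), zRef = 0,
            exprColumn = "blot", nPointsFit = 10L)
  expect_identical(cdData(applyDepthModel(tb, m0))$blot, d0$blot)
  expect_error(applyDepthModel(tb, new("DepthModel", decayRate = 0.1,
                                       scales = c(e = 1), zRef = 0,
                                       exprColumn = "gfp",
                                       nPointsFit = 10L)), "gfp")
})

test_that("correcting the training embryos flattens the depth trend", {
  tabs <- depthCohort(3)
  m <- fitDepthModel(tabs)
  corrected <- lapply(tabs, applyDepthModel, model = m)
  refit <- fitDepthModel(corrected)
  expect_lt(abs(decayRate(refit)), 0.005)
})

test_that("a fitted model transfers to held-out embryos", {
  cohortA <- depthCohort(4)
  m <- fitDepthModel(cohortA)
  heldout <- depthCohort(5, nEmb = 1)[[1L]]
  corr <- applyDepthModel(heldout, m)
  refit <- suppressWarnings(fitDepthModel(corr))
  expect_lt(abs(decayRate(refit)), 0.01)
})

test_that("depth models serialize byte-identically and reject bad files", {
  m <- fitDepthModel(depthCohort(6), zRef = 3.25)
  f1 <- tempfile(); f2 <- tempfile()
  writeDepthModel(m, f1)
  back <- readDepthModel(f1)
  expect_equal(decayRate(back), decayRate(m), tolerance = 0)
  expect_identical(back@scales, m@scales)
  expect_identical(back@zRef, m@zRef)
  expect_identical(back@nPointsFit, m@nPointsFit)
  writeDepthModel(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  writeLines(readLines(f1)[1:3], f2)
  expect_error(readDepthModel(f2), "truncated")
  txt <- readLines(f1)
  txt[2] <- "version: 99"
  writeLines(txt, f2)
  expect_error(readDepthModel(f2), "version")
})
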