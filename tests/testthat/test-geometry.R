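# Rigid-body orientation: PCA long axis, landmark sign/roll, isometry

test_that("an already-canonical embryo is a fixed point of the fitter", {
  sim <- simulateEmbryo(simulationParams(positionJitter = 0,
                                         noiseSigma = 0), seed = 1)
  tf <- fitOrientation(sim$truth$canonical, 22)
  expect_lt(sqrt(sum(tf@center^2)), 1e-9)
  expect_lt(max(abs(tf@rotation - diag(3))), 1e-9)
})

test_that("fitOrientation undoes a random pose exactly", {
  sim <- simulateEmbryo(simulationParams(positionJitter = 0,
                                         noiseSigma = 0), seed = 2)
  canon <- cdData(sim$truth$canonical)
  set.seed(99)
  for (rep in 1:5) {
    Q <- randomRotation()
    tr <- rnorm(3, sd = 20)
    d <- canon
    posed <- t(Q %*% t(as.matrix(d[, c("x", "y", "z")]))) +
      rep(tr, each = nrow(d))
    d$x <- posed[, 1]; d$y <- posed[, 2]; d$z <- posed[, 3]
    tb <- EmbryoTable(d, embryoId = "posed", coordUnits = "micron")
    rec <- cdData(applyTransform(tb, fitOrientation(tb, 22), "all"))
    rmsd <- sqrt(mean((rec$x - canon$x)^2 + (rec$y - canon$y)^2 +
                        (rec$z - canon$z)^2))
    expect_lt(rmsd, 1e-6)
  }
})

test_that("consistent roll landmarks agree; a single landmark is exact", {
  # dorsal and left exactly 90 degrees apart: both candidates identical
  tb <- rollConfigTable(list(dorsal = pi / 3, left = pi / 3 - pi / 2))
  tf <- fitOrientation(tb, 1, rollGroupsFor(list(dorsal = 0, left = 0)))
  expect_equal(wrapAngle(fittedRoll(tf) - (pi / 2 - pi / 3)), 0,
               tolerance = 1e-9)

  # with a single roll landmark its centroid lands exactly on the target
  tb2 <- rollConfigTable(list(dorsal = -1.1))
  tf2 <- fitOrientation(tb2, 1, rollGroupsFor(list(dorsal = 0)))
  out <- cdData(applyTransform(tb2, tf2, "all"))
  dors <- out[out$cell == "Caaa", ]
  expect_lt(abs(dors$y), 1e-9)
  expect_gt(dors$z, 0)
})

test_that("inconsistent roll landmarks average like grid minimisation", {
  set.seed(5)
  for (rep in 1:10) {
    base <- runif(1, -pi, pi)
    dev <- runif(3, -pi / 6, pi / 6)   # deviations < 30 degrees
    angles <- list(dorsal = pi / 2 - (base + dev[1]),
                   left = 0 - (base + dev[2]),
                   right = pi - (base + dev[3]))
    tb <- rollConfigTable(angles)
    tf <- fitOrientation(tb, 1,
                         rollGroupsFor(list(dorsal = 0, left = 0,
                                            right = 0)))
    expect_equal(wrapAngle(fittedRoll(tf) - gridRoll(base + dev)), 0,
                 tolerance = 0.01)
  }
})

test_that("fitOrientation validates its inputs", {
  tb <- rollConfigTable(list(dorsal = 1))
  px <- EmbryoTable(cdData(tb), coordUnits = "pixel")
  expect_error(fitOrientation(px, 1), "micron")
  expect_error(fitOrientation(tb, 99), "reference time")
  expect_error(fitOrientation(tb, 1, landmarkGroups(posterior = "MSaa")),
               "posterior")
  expect_error(
    fitOrientation(tb, 1, list(posterior = "Cxp")), "roll")

  # exactly degenerate long axis: octahedral cloud, equal eigenvalues
  oct <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0),
               c(0, 0, 5), c(0, 0, -5))
  d <- data.frame(cell = c("Cap", "Caaa", sprintf("n%d", 3:6)),
                  time = 1, x = oct[, 1], y = oct[, 2], z = oct[, 3])
  sph <- EmbryoTable(d, coordUnits = "micron")
  expect_error(fitOrientation(sph, 1), "ambiguous long axis")
})

test_that("applyTransform is an isometry with a working inverse", {
  idt <- new("RigidTransform", center = c(0, 0, 0), rotation = diag(3),
             referenceTime = 1)
  tb <- randomEmbryoTable(3)
  um <- applyMetadata(tb, EmbryoMetadata(0.1, 0.5))
  expect_tables_equal(applyTransform(um, idt, "all"), um, tol = 1e-12)

  set.seed(12)
  for (rep in 1:5) {
    Q <- randomRotation()
    tf <- new("RigidTransform", center = rnorm(3, sd = 10), rotation = Q,
              referenceTime = 1)
    moved <- applyTransform(um, tf, "all")
    d0 <- cdData(um); d1 <- cdData(moved)
    for (t in unique(d0$time)) {
      p0 <- as.matrix(d0[d0$time == t, c("x", "y", "z")])
      p1 <- as.matrix(d1[d1$time == t, c("x", "y", "z")])
      if (nrow(p0) < 2) next
      expect_lt(max(abs(dist(p0) - dist(p1))), 1e-9)
    }
    back <- applyTransform(moved, invertTransform(tf), "all")
    expect_equal(cdData(back)$x, d0$x, tolerance = 1e-9)
    expect_equal(cdData(back)$z, d0$z, tolerance = 1e-9)
  }

  # reference-only scope leaves other timepoints alone
  tf <- new("RigidTransform", center = c(1, 2, 3),
            rotation = embryoTrace:::.rollMatrix(0.5), referenceTime = 1)
  part <- applyTransform(um, tf, "reference")
  d0 <- cdData(um); d1 <- cdData(part)
  other <- d0$time != 1
  expect_identical(d1$x[other], d0$x[other])
  expect_false(isTRUE(all.equal(d1$x[!other], d0$x[!other])))
  tf9 <- new("RigidTransform", center = c(0, 0, 0), rotation = diag(3),
             referenceTime = 999)
  expect_error(applyTransform(um, tf9, "reference"), "999")
})

test_that("transforms serialize and restore exactly", {
  set.seed(8)
  tf <- new("RigidTransform", center = rnorm(3), rotation = randomRotation(),
            referenceTime = 22)
  f <- tempfile()
  writeTransform(tf, f)
  back <- readTransform(f)
  expect_identical(back@center, tf@center)
  expect_identical(back@rotation, tf@rotation)
  expect_identical(back@referenceTime, tf@referenceTime)
  writeLines(readLines(f)[1:3], f)
  expect_error(readTransform(f), "truncated")
})
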