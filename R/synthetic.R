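## Synthetic tracked embryos with known ground truth: a stereotyped
## division schedule, ellipsoid-scaled positions with the default landmark
## lineages at their anatomical half-axes by construction, a rigid
## orientation applied to the canonical frame, and lineage-programmed
## expression with exponential depth decay plus lognormal noise. Exists so
## every other module can be tested without external data; the schedule is
## a fixture constant, not a biological claim.

# per-founder division cadence (ordinal frames between birth and division)
.SIM_CADENCE <- c(AB = 3, MS = 4, E = 5, C = 4, D = 5)
# generations simulated below each founder (~100-cell stage by default)
.SIM_DEPTH <- c(AB = 5, MS = 4, E = 3, C = 4, D = 2)
# division-letter axis per generation under each founder (real lineages
# alternate anterior/posterior with left/right and dorsal/ventral splits)
.SIM_AXES <- list(AB = c("ap", "lr", "ap", "dv", "ap"),
                  MS = c("ap", "ap", "lr", "dv"),
                  E  = c("ap", "lr", "ap"),
                  C  = c("ap", "ap", "ap", "dv"),
                  D  = c("ap", "ap"))
# founder birth/division ordinals
.SIM_FOUNDER_SCHED <- data.frame(
  cell     = c("P0", "AB", "P1", "EMS", "P2", "MS", "E", "C", "P3",
               "D", "P4", "Z2", "Z3"),
  birth    = c(1, 3, 3, 5, 5, 8, 8, 7, 7, 10, 10, 13, 13),
  division = c(2, 5, 4, 7, 6, NA, NA, NA, NA, NA, NA, NA, NA),
  stringsAsFactors = FALSE)

# canonical-frame founder anchor positions (microns, AP = x, L = +y, D = +z)
.SIM_FOUNDER_POS <- rbind(
  P0 = c(0, 0, 0),    AB = c(10, 0, 1),  P1 = c(-8, 0, 0),
  EMS = c(-4, 0, -4), P2 = c(-12, 0, 2), MS = c(-2, 0, -5),
  E = c(-6, 0, -6),   C = c(-11, 0, 6),  P3 = c(-14, 0, -1),
  D = c(-14, 0, -3),  P4 = c(-16, 0, 0), Z2 = c(-17, 0, 1),
  Z3 = c(-16, 0, -1))

# chirality fix-ups: letter-based placement alone leaves the MS
# granddaughters mirror-symmetric in y, so the conventional right/left
# landmarks (MSap / MSpp) are nudged onto their half-axes explicitly
.SIM_BIAS <- list(MSap = c(0, -5, 0), MSpp = c(0, 5, 0),
                  MSaa = c(0, 2, 1), MSpa = c(0, -2, 1))

.AXIS_VECTORS <- list(a = c(1, 0, 0), p = c(-1, 0, 0),
                      l = c(0, 1, 0), r = c(0, -1, 0),
                      d = c(0, 0, 1), v = c(0, 0, -1))

#' Stereotyped division schedule for the simulator
#'
#' Expands the founder pedigree into a full (cell, birth, division) table:
#' each founder's sublineage divides at a fixed cadence down to a fixed
#' generation depth, with division letters following a per-generation
#' axis cycle (so the usual landmark names MSap, MSpp, Cap, Cpp, Caaa,
#' Cpaa all exist). Division times strictly increase along every path.
#'
#' @param tEnd last simulated timepoint; cells alive at tEnd simply end.
#' @return data.frame(cell, birth, division) with NA division for
#'   terminal cells.
#' @export
defaultSchedule <- function(tEnd = 26) {
  rows <- .SIM_FOUNDER_SCHED
  out <- list(rows)
  for (f in names(.SIM_CADENCE)) {
    cad <- .SIM_CADENCE[[f]]
    depth <- .SIM_DEPTH[[f]]
    axes <- .SIM_AXES[[f]]
    frontier <- data.frame(cell = f,
                           birth = rows$birth[rows$cell == f],
                           stringsAsFactors = FALSE)
    for (g in seq_len(depth)) {
      div <- frontier$birth + cad
      # mark the parents as dividing
      for (i in seq_len(nrow(frontier))) {
        nm <- frontier$cell[i]
        for (j in seq_along(out)) {
          hit <- out[[j]]$cell == nm
          if (any(hit)) out[[j]]$division[hit] <- div[i]
        }
      }
      letters2 <- strsplit(axes[g], "")[[1L]]
      kids <- data.frame(
        cell = as.vector(t(outer(frontier$cell, letters2, paste0))),
        birth = rep(div + 1, each = 2L),
        division = NA_real_, stringsAsFactors = FALSE)
      out <- c(out, list(kids))
      frontier <- kids[, c("cell", "birth")]
      if (all(frontier$birth > tEnd)) break
    }
  }
  sched <- do.call(rbind, out)
  sched <- sched[sched$birth <= tEnd, , drop = FALSE]
  sched$division[!is.na(sched$division) & sched$division > tEnd] <- NA
  rownames(sched) <- NULL
  sched
}

#' Simulation parameters
#'
#' Defaults are the conditions the package is tested under: a ~100-cell
#' stereotyped schedule, a 50 x 30 x 30 micron ellipsoid, decay rate
#' k = 0.04 per micron, lognormal noise sigma = 0.1 and 1 micron placement
#' jitter, with an MS/E-restricted expression program over a low baseline.
#'
#' @param schedule division schedule (see \code{\link{defaultSchedule}}).
#' @param semiAxes ellipsoid semi-axes in microns.
#' @param rotation,translation rigid orientation applied to the canonical
#'   frame (the "acquisition pose").
#' @param expressionProgram list of list(pattern, onset, level) rules,
#'   first match (including descendants) wins.
#' @param baseline level for cells matching no rule.
#' @param decayRate depth decay k (1/micron).
#' @param noiseSigma lognormal sigma (log scale).
#' @param positionJitter placement jitter s.d. (microns).
#' @param tEnd last simulated timepoint.
#' @param exprColumn emitted expression column name.
#' @return a \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(schedule = defaultSchedule(tEnd),
                             semiAxes = c(25, 15, 15),
                             rotation = diag(3),
                             translation = c(0, 0, 0),
                             expressionProgram = list(
                               list(pattern = "MS", onset = 8, level = 500),
                               list(pattern = "E", onset = 9, level = 800)),
                             baseline = 20,
                             decayRate = 0.04,
                             noiseSigma = 0.1,
                             positionJitter = 1,
                             tEnd = 26,
                             exprColumn = "blot") {
  new("SimulationParams", schedule = schedule,
      semiAxes = as.numeric(semiAxes), rotation = rotation,
      translation = as.numeric(translation),
      expressionProgram = expressionProgram,
      baseline = as.numeric(baseline), decayRate = as.numeric(decayRate),
      noiseSigma = as.numeric(noiseSigma),
      positionJitter = as.numeric(positionJitter), tEnd = as.numeric(tEnd),
      exprColumn = exprColumn)
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) (QR of a Gaussian matrix, sign-fixed, reflected to
#' det +1 if needed). Uses the current RNG stream.
#'
#' @return 3x3 proper orthogonal matrix.
#' @export
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

# canonical-frame positions for every cell in the schedule: founders at
# anchor positions, daughters displaced along their division-letter axis
# with shrinking magnitude plus isotropic jitter
.simPositions <- function(sched, jitter) {
  pos <- matrix(NA_real_, nrow(sched), 3L,
                dimnames = list(sched$cell, c("x", "y", "z")))
  parsed <- parseLineageName(sched$cell)
  ord <- order(nchar(sched$cell))
  for (i in ord) {
    nm <- sched$cell[i]
    if (nm %in% rownames(.SIM_FOUNDER_POS)) {
      p <- .SIM_FOUNDER_POS[nm, ]
    } else {
      par <- suppressWarnings(parentOf(nm))
      p <- pos[par, ]
      last <- substr(parsed$suffix[i], nchar(parsed$suffix[i]),
                     nchar(parsed$suffix[i]))
      mag <- 9 * 0.6^nchar(parsed$suffix[i])
      p <- p + .AXIS_VECTORS[[last]] * mag
      if (!is.null(.SIM_BIAS[[nm]])) p <- p + .SIM_BIAS[[nm]]
    }
    pos[i, ] <- p + stats::rnorm(3, sd = jitter)
  }
  pos
}

# first matching program rule (with descendants) for each cell, else baseline
.simLevels <- function(cells, program, baseline) {
  lev <- rep(baseline, length(cells))
  onset <- rep(-Inf, length(cells))
  done <- rep(FALSE, length(cells))
  for (rule in program) {
    sel <- suppressWarnings(
      selectCells(cells, rule$pattern, includeDescendants = TRUE))
    hit <- !done & cells %in% sel
    lev[hit] <- rule$level
    onset[hit] <- rule$onset
    done[hit] <- TRUE
  }
  list(level = lev, onset = onset)
}

#' Simulate one tracked embryo with known ground truth
#'
#' Places every scheduled cell in the canonical anatomical frame (AP along
#' x; the default landmark lineages sit on their target half-axes by
#' construction), canonicalises that frame so it is an exact fixed point
#' of \code{\link{fitOrientation}}, then applies the acquisition pose
#' (params rotation + translation, shifted so all coordinates are
#' positive, as a real image stack's are). Expression after each rule's
#' onset is \code{level * exp(-k z) * lognormal(sigma)} with z the emitted
#' (depth-axis) coordinate.
#'
#' @param params a \code{\link{simulationParams}} object.
#' @param seed integer seed; identical seeds give identical output.
#' @param tRef reference time used to canonicalise the frame (default 22,
#'   when all default landmark lineages are populated).
#' @return list with elements \code{table} (an
#'   \linkS4class{EmbryoTable}, micron units, ordinal time) and
#'   \code{truth} (canonical table, pose rotation/translation, decay rate,
#'   schedule, reference time).
#' @export
simulateEmbryo <- function(params = simulationParams(), seed = 1L,
                           tRef = 22) {
  stopifnot(is(params, "SimulationParams"))
  set.seed(seed)
  sched <- params@schedule
  pos <- .simPositions(sched, params@positionJitter)
  # scale into the ellipsoid envelope
  half <- apply(abs(pos), 2L, max)
  pos <- sweep(pos, 2L, params@semiAxes * 0.9 / pmax(half, 1e-9), `*`)

  times <- seq_len(params@tEnd)
  live <- lapply(times, function(t)
    which(sched$birth <= t &
            (is.na(sched$division) | sched$division >= t)))
  rows <- data.frame(
    cell = sched$cell[unlist(live)],
    time = rep(times, lengths(live)),
    stringsAsFactors = FALSE)
  p <- pos[rows$cell, , drop = FALSE]
  rows$x <- p[, 1L]; rows$y <- p[, 2L]; rows$z <- p[, 3L]

  canon <- EmbryoTable(rows, embryoId = sprintf("sim%d", seed),
                       coordUnits = "micron", timeUnits = "ordinal")
  # make the canonical frame an exact fixed point of the fitter
  tf0 <- fitOrientation(canon, tRef = tRef)
  canon <- applyTransform(canon, tf0, scope = "all")

  # acquisition pose: rotate/translate, then shift positive like a stack
  d <- cdData(canon)
  emitted <- t(params@rotation %*% t(as.matrix(d[, c("x", "y", "z")])))
  emitted <- sweep(emitted, 2L, params@translation, `+`)
  shift <- pmax(0, -apply(emitted, 2L, min)) + 2
  emitted <- sweep(emitted, 2L, shift, `+`)
  d$x <- emitted[, 1L]; d$y <- emitted[, 2L]; d$z <- emitted[, 3L]

  prog <- .simLevels(sched$cell, params@expressionProgram, params@baseline)
  ix <- match(d$cell, sched$cell)
  base <- ifelse(d$time >= prog$onset[ix], prog$level[ix], params@baseline)
  noise <- exp(stats::rnorm(nrow(d), 0, params@noiseSigma))
  d[[params@exprColumn]] <- base * exp(-params@decayRate * d$z) * noise
  d$diameter <- pmax(1, 8 * 0.8^nchar(d$cell))

  table <- EmbryoTable(d, embryoId = sprintf("sim%d", seed),
                       coordUnits = "micron", timeUnits = "ordinal")
  cn <- cdData(canon)
  list(table = table,
       truth = list(canonical = canon,
                    rotation = params@rotation,
                    translation = params@translation + shift,
                    shift = shift,
                    decayRate = params@decayRate,
                    schedule = sched,
                    expression = prog,
                    referenceTime = tRef))
}

#' Simulate replicate embryos
#'
#' Independent draws sharing the schedule, decay rate and expression
#' program, each with its own random acquisition pose and noise stream.
#'
#' @param params a \code{\link{simulationParams}} object (its rotation and
#'   translation are replaced per replicate unless
#'   \code{varyOrientation = FALSE}).
#' @param n number of replicates (>= 1).
#' @param seeds integer seeds, one per replicate (default 1..n).
#' @param varyOrientation draw a random acquisition pose per replicate
#'   (default TRUE); with FALSE, \code{n = 1} reproduces
#'   \code{simulateEmbryo(params, seeds[1])} exactly.
#' @return list of \code{simulateEmbryo} results.
#' @export
simulateReplicates <- function(params = simulationParams(), n = 3L,
                               seeds = seq_len(n),
                               varyOrientation = TRUE) {
  stopifnot(n >= 1L, length(seeds) == n)
  lapply(seq_len(n), function(i) {
    if (varyOrientation) {
      set.seed(seeds[i] + 10000L)
      params@rotation <- randomRotation()
      params@translation <- stats::rnorm(3, sd = 5)
    }
    simulateEmbryo(params, seed = seeds[i])
  })
}
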