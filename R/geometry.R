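## Rigid-body orientation: PCA finds the embryo's long (AP) axis, landmark
## cell groups fix the AP sign and the roll about that axis. Canonical
## frame: anterior = +x, left = +y, dorsal = +z (right-handed).

# rotation taking unit vector u onto unit vector v (Rodrigues)
.rotationBetween <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to u
    perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * u) * u
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * K %*% K
}

# rotation about +x by theta: a point at angle alpha = atan2(z, y) in the
# y-z plane moves to alpha + theta
.rollMatrix <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(1, 0, 0,
           0, ct, st,
           0, -st, ct), 3, 3)
}

# average of angles: circular mean refined by the mean wrapped deviation,
# which is the exact minimiser of the summed squared (wrapped) angular
# deviation whenever all candidates lie within pi of the result
.circularMean <- function(theta) {
  c0 <- atan2(mean(sin(theta)), mean(cos(theta)))
  wrapped <- atan2(sin(theta - c0), cos(theta - c0))
  c1 <- c0 + mean(wrapped)
  atan2(sin(c1), cos(c1))
}

# target angle in the y-z plane (measured from +y toward +z) per group
.ROLL_TARGETS <- c(left = 0, dorsal = pi / 2, right = pi, ventral = -pi / 2)

#' Landmark cell groups for orientation fitting
#'
#' Named lists of Sulston patterns marking anatomical directions. At least
#' one of anterior/posterior fixes the AP sign; at least one of
#' dorsal/ventral/left/right fixes the roll about the AP axis. The default
#' groups are the conventional C and MS sublineages: posterior = Cxp,
#' dorsal = Cxaa, right = MSap, left = MSpp. Patterns select observed cells
#' including their descendants, so the groups remain usable after those
#' cells divide.
#'
#' @param anterior,posterior,dorsal,ventral,left,right character vectors of
#'   Sulston patterns, or NULL.
#' @return a named list of pattern vectors.
#' @export
landmarkGroups <- function(anterior = NULL, posterior = "Cxp",
                           dorsal = "Cxaa", ventral = NULL,
                           left = "MSpp", right = "MSap") {
  g <- list(anterior = anterior, posterior = posterior, dorsal = dorsal,
            ventral = ventral, left = left, right = right)
  g[!vapply(g, is.null, logical(1))]
}

# positions matrix (rows = cells) at one timepoint
.positionsAt <- function(table, t) {
  d <- cdData(table)
  d <- d[d$time == t, , drop = FALSE]
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$cell
  m
}

.groupCentroid <- function(pos, group, patterns) {
  sel <- .inLineageOf(rownames(pos), patterns)
  if (!any(sel))
    stop(sprintf("landmark group '%s' (%s) matches no cells at the reference time",
                 group, paste(patterns, collapse = ", ")))
  colMeans(pos[sel, , drop = FALSE])
}

#' Fit the rigid-body orientation of an embryo
#'
#' At the reference timepoint, PCA on the nuclear positions identifies the
#' embryo's long (AP) axis; the anterior/posterior landmark group fixes its
#' sign (anterior = +x). The roll about the AP axis is then set from the
#' provided dorsal/ventral/left/right groups: each group yields a candidate
#' roll angle placing its centroid direction on its target half-axis
#' (dorsal +z, ventral -z, left +y, right -y), and the final roll is the
#' average of those candidates (a circular mean refined to the exact
#' least-squares angular mean, i.e. the roll minimising the summed squared
#' angular deviation of the groups from their targets). With mutually
#' inconsistent groups neither ends up exactly on its axis; that
#' compromise is intended.
#'
#' @param table an \linkS4class{EmbryoTable} in micron units.
#' @param tRef the reference timepoint (present in the table).
#' @param groups landmark groups from \code{\link{landmarkGroups}}.
#' @return a \linkS4class{RigidTransform}.
#' @seealso \code{\link{applyTransform}}
#' @export
fitOrientation <- function(table, tRef, groups = landmarkGroups()) {
  stopifnot(is(table, "EmbryoTable"))
  if (coordUnits(table) != "micron")
    stop("orientation fitting requires micron coordinates; run applyMetadata first")
  if (!any(cdData(table)$time == tRef))
    stop(sprintf("reference time %g not present in embryo '%s'",
                 tRef, embryoId(table)))
  ap_groups <- intersect(names(groups), c("anterior", "posterior"))
  roll_groups <- intersect(names(groups),
                           c("dorsal", "ventral", "left", "right"))
  if (!length(ap_groups))
    stop("need an anterior or posterior landmark group to fix the AP sign")
  if (!length(roll_groups))
    stop("need at least one of dorsal/ventral/left/right to fix the roll")
  P <- .positionsAt(table, tRef)
  if (nrow(P) < 4L)
    stop(sprintf("need >= 4 cells at the reference time, found %d", nrow(P)))
  ctr <- colMeans(P)
  Pc <- sweep(P, 2L, ctr)
  ev <- eigen(stats::cov(Pc), symmetric = TRUE)
  lam <- ev$values
  if ((lam[1L] - lam[2L]) / lam[1L] < 1e-6)
    stop("ambiguous long axis: two leading principal components are equal")
  u <- ev$vectors[, 1L]

  cents <- lapply(stats::setNames(nm = names(groups)), function(g)
    .groupCentroid(P, g, groups[[g]]) - ctr)
  # AP sign: anterior projects positive / posterior negative
  proj <- 0
  if ("anterior" %in% ap_groups) proj <- proj + sum(cents$anterior * u)
  if ("posterior" %in% ap_groups) proj <- proj - sum(cents$posterior * u)
  if (proj < 0) u <- -u

  R1 <- .rotationBetween(u, c(1, 0, 0))
  thetas <- vapply(roll_groups, function(g) {
    v <- as.numeric(R1 %*% cents[[g]])
    if (sqrt(v[2]^2 + v[3]^2) < 1e-12)
      stop(sprintf("landmark group '%s' lies on the AP axis; roll undefined", g))
    .ROLL_TARGETS[[g]] - atan2(v[3], v[2])
  }, numeric(1))
  theta <- .circularMean(thetas)
  R <- .rollMatrix(theta) %*% R1
  new("RigidTransform", center = as.numeric(ctr), rotation = R,
      referenceTime = as.numeric(tRef))
}

#' Apply a rigid transform to an embryo table
#'
#' Maps each in-scope position p to \code{rotation (p - center)}; all other
#' fields are untouched. The transform is an isometry: pairwise inter-cell
#' distances at each timepoint are preserved, and at the reference time the
#' centroid maps to the origin.
#'
#' @param table an \linkS4class{EmbryoTable} in micron units.
#' @param tf a \linkS4class{RigidTransform}.
#' @param scope \code{"all"} rotates every timepoint (full-embryo
#'   rotation); \code{"reference"} rotates only the transform's reference
#'   timepoint.
#' @return the transformed \linkS4class{EmbryoTable}.
#' @export
applyTransform <- function(table, tf, scope = c("all", "reference")) {
  stopifnot(is(table, "EmbryoTable"), is(tf, "RigidTransform"))
  scope <- match.arg(scope)
  if (coordUnits(table) != "micron")
    stop("applyTransform requires micron coordinates")
  d <- cdData(table)
  idx <- if (scope == "all") seq_len(nrow(d)) else which(d$time == tf@referenceTime)
  if (scope == "reference" && !length(idx))
    stop(sprintf("reference time %g absent from embryo '%s'",
                 tf@referenceTime, embryoId(table)))
  if (length(idx)) {
    pos <- t(as.matrix(d[idx, c("x", "y", "z")]))
    newpos <- tf@rotation %*% (pos - tf@center)
    d$x[idx] <- newpos[1L, ]
    d$y[idx] <- newpos[2L, ]
    d$z[idx] <- newpos[3L, ]
  }
  setEmbryoData(table, d)
}

#' Invert a rigid transform
#'
#' @param tf a \linkS4class{RigidTransform}.
#' @return the transform mapping canonical coordinates back to the raw
#'   frame (note its center is 0 and it adds the original center back via
#'   composition; use with \code{\link{applyTransform}}).
#' @export
invertTransform <- function(tf) {
  stopifnot(is(tf, "RigidTransform"))
  # inverse of p -> R (p - c) is q -> R' q + c = R' (q - (-R c))
  new("RigidTransform", center = as.numeric(-tf@rotation %*% tf@center),
      rotation = t(tf@rotation), referenceTime = tf@referenceTime)
}

#' Serialize a rigid transform to a small text file
#'
#' Key-value text with full numeric precision; round-trips exactly through
#' \code{\link{readTransform}}.
#'
#' @param tf a \linkS4class{RigidTransform}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTransform <- function(tf, path) {
  stopifnot(is(tf, "RigidTransform"))
  fmt <- function(v) paste(formatC(v, format = "g", digits = 17),
                           collapse = " ")
  lines <- c("# embryoTrace rigid transform v1",
             "version: 1",
             sprintf("reference_time: %s", fmt(tf@referenceTime)),
             sprintf("center: %s", fmt(tf@center)),
             sprintf("rotation: %s", fmt(as.numeric(t(tf@rotation)))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  kv <- .readKeyValues(path, "rigid transform")
  if (!identical(kv[["version"]], "1"))
    stop(sprintf("unsupported transform file version: %s",
                 kv[["version"]]))
  num <- function(key) {
    if (is.null(kv[[key]]))
      stop(sprintf("transform file %s is truncated: missing '%s'",
                   basename(path), key))
    as.numeric(strsplit(trimws(kv[[key]]), " +")[[1L]])
  }
  new("RigidTransform", center = num("center"),
      rotation = matrix(num("rotation"), 3, 3, byrow = TRUE),
      referenceTime = num("reference_time"))
}

# shared key-value text reader for small model/transform files
.readKeyValues <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    stop(sprintf("%s file %s is empty or truncated", what, basename(path)))
  kv <- list()
  for (ln in lines) {
    ix <- regexpr(":", ln, fixed = TRUE)
    if (ix < 0)
      stop(sprintf("%s file %s: malformed line '%s'", what,
                   basename(path), ln))
    kv[[trimws(substr(ln, 1L, ix - 1L))]] <-
      trimws(substring(ln, ix + 1L))
  }
  kv
}
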