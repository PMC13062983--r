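## Exponential depth-attenuation correction. Fluorescence intensity decays
## approximately exponentially with imaging depth; a shared decay rate is
## learned across replicate embryos (log-linear least squares with one
## intercept per embryo) and expression is corrected to a common reference
## depth. Fit before any 3D rotation: z must still mean imaging depth.

#' Fit an exponential depth-decay model across replicate embryos
#'
#' Fits \code{log E = a_i - k z} by ordinary least squares over all rows
#' with positive expression, with the slope \code{k} shared across embryos
#' and one intercept \code{a_i} per embryo (absorbing brightness
#' differences between recordings). Tables must be in microns and must not
#' have been rotated to the canonical frame — z has to remain the optical
#' depth axis.
#'
#' @param tables one \linkS4class{EmbryoTable} or a list of replicates.
#' @param exprColumn expression column to model (default \code{"blot"}).
#' @param zRef reference depth in microns for later correction (default 0,
#'   the top of the stack, so correction only boosts when k > 0).
#' @return a \linkS4class{DepthModel}.
#' @seealso \code{\link{applyDepthModel}}, \code{\link{writeDepthModel}}
#' @export
fitDepthModel <- function(tables, exprColumn = "blot", zRef = 0) {
  if (is(tables, "EmbryoTable")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "EmbryoTable")))
  if (length(tables) < 2L)
    warning("fitting a depth model on a single embryo; replicates are recommended")
  parts <- lapply(tables, function(tb) {
    if (coordUnits(tb) != "micron")
      stop(sprintf("embryo '%s' is not in micron units", embryoId(tb)))
    d <- cdData(tb)
    if (!(exprColumn %in% names(d)))
      stop(sprintf("expression column '%s' absent from embryo '%s'",
                   exprColumn, embryoId(tb)))
    data.frame(emb = embryoId(tb), z = d$z, E = d[[exprColumn]],
               stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, parts)
  dat <- dat[!is.na(dat$E) & dat$E > 0, , drop = FALSE]
  if (nrow(dat) < 10L)
    stop(sprintf("need >= 10 positive-expression points to fit, found %d",
                 nrow(dat)))
  if (diff(range(dat$z)) == 0)
    stop("no depth range: all z values identical")
  dat$emb <- factor(dat$emb)
  if (nlevels(dat$emb) > 1L) {
    fit <- stats::lm(log(E) ~ 0 + emb + z, data = dat)
    co <- stats::coef(fit)
    a <- co[names(co) != "z"]
    names(a) <- sub("^emb", "", names(a))
  } else {
    fit <- stats::lm(log(E) ~ z, data = dat)
    co <- stats::coef(fit)
    a <- stats::setNames(co[["(Intercept)"]], levels(dat$emb))
  }
  k <- -unname(co[["z"]])
  new("DepthModel", decayRate = k, scales = a, zRef = as.numeric(zRef),
      exprColumn = exprColumn, nPointsFit = nrow(dat))
}

#' Correct expression to the model's reference depth
#'
#' Every value in the model's expression column is multiplied by
#' \code{exp(k (z - zRef))}; positions are untouched. Only the shared decay
#' rate and reference depth are used, so the model transfers to embryos
#' outside the training set (acquired with equivalent imaging). The
#' corrected values replace the expression column; the original is kept
#' under a \code{"_raw"} suffix. Non-positive values, excluded from
#' fitting, are still corrected (the multiplicative factor is defined for
#' any value).
#'
#' @param table an \linkS4class{EmbryoTable} in microns, same acquisition
#'   convention (unrotated z) as the training data.
#' @param model a \linkS4class{DepthModel}.
#' @return the corrected \linkS4class{EmbryoTable}.
#' @export
applyDepthModel <- function(table, model) {
  stopifnot(is(table, "EmbryoTable"), is(model, "DepthModel"))
  if (coordUnits(table) != "micron")
    stop("applyDepthModel requires micron coordinates")
  col <- model@exprColumn
  d <- cdData(table)
  if (!(col %in% names(d)))
    stop(sprintf("expression column '%s' absent from embryo '%s'",
                 col, embryoId(table)))
  raw_col <- paste0(col, "_raw")
  d[[raw_col]] <- d[[col]]
  d[[col]] <- d[[col]] * exp(model@decayRate * (d$z - model@zRef))
  out <- setEmbryoData(table, d)
  out@exprColumns <- union(exprColumns(table), c(col, raw_col))
  validObject(out)
  out
}

#' Serialize / restore a depth model
#'
#' Small key-value text format holding the decay rate, reference depth,
#' expression column, fit size and per-embryo intercepts, at full numeric
#' precision: save -> load -> save is byte-identical.
#'
#' @param model a \linkS4class{DepthModel}.
#' @param path file path.
#' @return \code{writeDepthModel}: invisibly, \code{path};
#'   \code{readDepthModel}: the restored \linkS4class{DepthModel}.
#' @export
writeDepthModel <- function(model, path) {
  stopifnot(is(model, "DepthModel"))
  g17 <- function(v) formatC(v, format = "g", digits = 17)
  lines <- c("# embryoTrace depth model v1",
             "version: 1",
             sprintf("decay_rate: %s", g17(model@decayRate)),
             sprintf("z_ref: %s", g17(model@zRef)),
             sprintf("expr_column: %s", model@exprColumn),
             sprintf("n_points_fit: %d", model@nPointsFit),
             vapply(names(model@scales), function(id)
               sprintf("scale %s: %s", id, g17(model@scales[[id]])),
               character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname writeDepthModel
#' @export
readDepthModel <- function(path) {
  kv <- .readKeyValues(path, "depth model")
  if (is.null(kv[["version"]]))
    stop(sprintf("depth model file %s is truncated: missing 'version'",
                 basename(path)))
  if (!identical(kv[["version"]], "1"))
    stop(sprintf("unsupported depth model version: %s", kv[["version"]]))
  need <- c("decay_rate", "z_ref", "expr_column", "n_points_fit")
  absent <- need[!need %in% names(kv)]
  if (length(absent))
    stop(sprintf("depth model file %s is truncated: missing %s",
                 basename(path), paste(absent, collapse = ", ")))
  scale_keys <- grep("^scale ", names(kv), value = TRUE)
  scales <- vapply(scale_keys, function(k) as.numeric(kv[[k]]), numeric(1))
  names(scales) <- sub("^scale ", "", scale_keys)
  new("DepthModel",
      decayRate = as.numeric(kv[["decay_rate"]]),
      scales = scales,
      zRef = as.numeric(kv[["z_ref"]]),
      exprColumn = kv[["expr_column"]],
      nPointsFit = as.integer(kv[["n_points_fit"]]))
}
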