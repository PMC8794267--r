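#' Construct a phase field from an array
#'
#' @param values 3D numeric array matching the grid
#' @param grid a \code{GridSpec}
#' @return a \code{\linkS4class{PhaseField}}
#' @export
PhaseField <- function(values, grid) {
  new("PhaseField", values = values, grid = grid)
}

#' @describeIn PhaseField the raw 3D array
#' @param x a \code{PhaseField}
#' @export
fieldValues <- function(x) x@values

#' Initialise a spherical cell
#'
#' Radial tanh profile 0.5 (1 + tanh(k (r0 - |r - center|))) with the
#' equilibrium interface steepness k = sqrt(c/2) in lattice units by
#' default, so a freshly seeded cell is already close to the stationary
#' profile of the surface-energy functional.  The radius r0 is implied by
#' the requested volume; the voxel-integrated volume is within 2% of the
#' request for radii well above the interface width.
#'
#' @param grid a \code{GridSpec}
#' @param center sphere centre, micrometres
#' @param volume requested volume, cubic micrometres
#' @param steepness interface steepness k, per voxel
#' @return a \code{PhaseField}
#' @export
cellSphere <- function(grid, center, volume, steepness = sqrt(1 / 2)) {
  stopifnot(is(grid, "GridSpec"), volume > 0)
  vLat <- volume / grid@dl^3
  r0 <- (3 * vLat / (4 * pi))^(1 / 3)        # voxels
  ax <- gridAxes(grid)
  ext <- grid@dl * (r0 + 2 / steepness)
  if (any(center - ext < c(min(ax$x), min(ax$y), min(ax$z))) ||
      any(center + ext > c(max(ax$x), max(ax$y), max(ax$z))))
    stop("sphere (incl. interface halo) exceeds the grid")
  dx2 <- ((ax$x - center[1]) / grid@dl)^2
  dy2 <- ((ax$y - center[2]) / grid@dl)^2
  dz2 <- ((ax$z - center[3]) / grid@dl)^2
  build <- function(r0) {
    vals <- array(0, dim = grid@dims)
    for (k in seq_along(dz2)) {
      r <- sqrt(outer(dx2, dy2, "+") + dz2[k])
      vals[, , k] <- 0.5 * (1 + tanh(steepness * (r0 - r)))
    }
    vals
  }
  # the smeared tail inflates the integral for small radii; correct the
  # nominal radius by fixed-point iteration on the integrated volume
  vals <- build(r0)
  for (it in 1:3) {
    v <- sum(vals)
    if (abs(v / vLat - 1) < 5e-3) break
    r0 <- r0 * (vLat / v)^(1 / 3)
    vals <- build(r0)
  }
  PhaseField(vals, grid)
}

#' Discrete Laplacian (7-point stencil, unit lattice spacing)
#'
#' Replicate-edge boundaries; exact for quadratics on interior voxels.
#'
#' @param f a \code{PhaseField}
#' @return a \code{PhaseField} of the same shape
#' @export
fieldLaplacian <- function(f) {
  stopifnot(is(f, "PhaseField"))
  out <- cpp_laplacian(as.vector(f@values), f@grid@dims)
  dim(out) <- f@grid@dims
  PhaseField(out, f@grid)
}

#' Discrete gradient (central differences, unit lattice spacing)
#'
#' @param f a \code{PhaseField}
#' @return list of three arrays x, y, z (lattice units per voxel)
#' @export
fieldGradient <- function(f) {
  stopifnot(is(f, "PhaseField"))
  gr <- cpp_gradient(as.vector(f@values), f@grid@dims)
  lapply(gr, function(gc) { dim(gc) <- f@grid@dims; gc })
}

#' Integrated field volume
#'
#' @param f a \code{PhaseField}
#' @param physical if TRUE (default) return cubic micrometres, else the
#'   lattice-unit sum of values
#' @return volume
#' @export
fieldVolume <- function(f, physical = TRUE) {
  v <- sum(f@values)
  if (physical) v * f@grid@dl^3 else v
}

#' Intensity-weighted centre of mass
#'
#' @param f a \code{PhaseField}
#' @return physical coordinate (micrometres), length 3
#' @export
centerOfMass <- function(f) {
  stopifnot(is(f, "PhaseField"))
  v <- f@values
  m <- sum(v)
  if (m <= 0) stop("degenerate field: zero mass")
  ax <- gridAxes(f@grid)
  sx <- sum(rowSums(v, dims = 1L) * ax$x)
  sy <- sum(rowSums(colSums(v, dims = 1L)) * ax$y)
  sz <- sum(colSums(v, dims = 2L) * ax$z)
  c(sx, sy, sz) / m
}

#' Numerical-health summary of a field
#'
#' Phase fields are not clamped; this reports the overshoot beyond the
#' nominal [0, 1] range and whether it exceeds the warning band
#' [-0.05, 1.05].
#'
#' @param f a \code{PhaseField}
#' @return list(min, max, healthy)
#' @export
fieldHealth <- function(f) {
  rng <- range(f@values)
  list(min = rng[1], max = rng[2],
       healthy = is.finite(rng[1]) && is.finite(rng[2]) &&
         rng[1] >= -0.05 && rng[2] <= 1.05)
}

#' Trilinear interpolation of a field at physical points
#'
#' @param f a \code{PhaseField}
#' @param pts n x 3 matrix of physical coordinates (micrometres)
#' @return numeric vector of interpolated values (replicate-edge outside)
#' @export
interpField <- function(f, pts) {
  pts <- matrix(pts, ncol = 3)
  g <- f@grid
  # continuous voxel coordinates, 0-based
  u <- sweep(pts, 2, g@origin, "-") / g@dl
  v <- f@values
  d <- g@dims
  i0 <- pmin(pmax(floor(u), 0), matrix(rep(d - 2, each = nrow(u)), ncol = 3))
  fr <- u - i0
  fr <- pmin(pmax(fr, 0), 1)
  idx <- function(ox, oy, oz) {
    cbind(i0[, 1] + ox + 1, i0[, 2] + oy + 1, i0[, 3] + oz + 1)
  }
  out <- 0
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    w <- (if (ox) fr[, 1] else 1 - fr[, 1]) *
         (if (oy) fr[, 2] else 1 - fr[, 2]) *
         (if (oz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * v[idx(ox, oy, oz)]
  }
  out
}

#' Construct an embryo state
#'
#' @param cells list of \code{CellState}
#' @param eggshell eggshell \code{PhaseField}
#' @param step simulation clock (steps)
#' @return an \code{\linkS4class{EmbryoState}}
#' @export
EmbryoState <- function(cells, eggshell, step = 0L) {
  new("EmbryoState", cells = cells, eggshell = eggshell,
      grid = eggshell@grid, step = as.integer(step))
}

#' Construct a cell state
#'
#' @param name lineage name
#' @param field the cell's \code{PhaseField}
#' @param targetVolume prescribed volume, cubic micrometres
#' @param birthStep step at which the cell appeared
#' @return a \code{\linkS4class{CellState}}
#' @export
CellState <- function(name, field, targetVolume, birthStep = 0L) {
  new("CellState", name = name, field = field,
      targetVolume = targetVolume, birthStep = as.integer(birthStep))
}

#' Cell names of an embryo
#' @param embryo an \code{EmbryoState}
#' @export
cellNames <- function(embryo) {
  vapply(embryo@cells, function(c) c@name, character(1))
}

#' Look up one cell of an embryo by name
#' @param embryo an \code{EmbryoState}
#' @param name cell name
#' @return a \code{CellState}
#' @export
getCell <- function(embryo, name) {
  i <- match(name, cellNames(embryo))
  if (is.na(i)) stop(sprintf("no cell named '%s'", name))
  embryo@cells[[i]]
}

setMethod("show", "PhaseField", function(object) {
  rng <- range(object@values)
  cat(sprintf("PhaseField %s, dl = %g um, values in [%.4g, %.4g], volume %.4g um^3\n",
              paste(object@grid@dims, collapse = "x"), object@grid@dl,
              rng[1], rng[2], fieldVolume(object)))
})

setMethod("show", "EmbryoState", function(object) {
  nm <- cellNames(object)
  cat(sprintf("EmbryoState: %d cell(s) [%s] on %s grid, step %d\n",
              length(nm), paste(nm, collapse = ", "),
              paste(object@grid@dims, collapse = "x"), object@step))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec %s, dl = %g um/voxel, origin (%s) um\n",
              paste(object@dims, collapse = "x"), object@dl,
              paste(signif(object@origin, 5), collapse = ", ")))
})
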