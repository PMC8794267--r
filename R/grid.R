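#' Construct a grid specification
#'
#' @param dims integer(3): voxels along x (A-P), y (L-R), z (D-V).  The
#'   reference grid of the compressed-embryo runs is \code{c(256, 128, 256)}
#'   at \code{dl = 0.2508}: the short dimension is the compressed left-right
#'   axis.
#' @param dl voxel pitch, micrometres
#' @param origin physical coordinate of the first voxel centre; defaults to
#'   centring the lattice on (0, 0, 0)
#' @return a \code{\linkS4class{GridSpec}}
#' @examples
#' g <- GridSpec(c(64, 32, 64), dl = 1.0032)
#' @export
GridSpec <- function(dims, dl, origin = -(dims - 1) / 2 * dl) {
  new("GridSpec", dims = as.integer(dims), dl = as.numeric(dl),
      origin = as.numeric(origin))
}

#' Voxel-centre coordinates along each axis
#'
#' @param grid a \code{GridSpec}
#' @return list of numeric vectors x, y, z (micrometres)
#' @export
gridAxes <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  # evaluated about the lattice midpoint so that coordinates of mirrored
  # voxel pairs are exact negations (up to the midpoint offset), keeping
  # mirror symmetries of fields built from them exact in floating point
  ax1 <- function(d) {
    n <- grid@dims[d]
    m <- (n - 1) / 2
    (seq_len(n) - 1 - m) * grid@dl + (grid@origin[d] + m * grid@dl)
  }
  list(x = ax1(1L), y = ax1(2L), z = ax1(3L))
}

#' Construct an eggshell specification
#'
#' Reference values from size measurements on compressed wild-type embryos:
#' semi-axes 27.5837 um (x) and 18.3477 um (z), compressed by 16.7942 um in
#' total along y, i.e. a half width of 9.9506 um.
#'
#' @param semiAxisX,semiAxisZ spheroid semi-axes, micrometres
#' @param yHalfWidth left-right half width (defaults to semiAxisZ: no
#'   clipping)
#' @param compressed logical; is the y clipping active?
#' @param center eggshell centre, micrometres
#' @return an \code{\linkS4class{EggshellSpec}}
#' @export
EggshellSpec <- function(semiAxisX = 27.5837, semiAxisZ = 18.3477,
                         yHalfWidth = semiAxisZ, compressed = yHalfWidth < semiAxisZ,
                         center = c(0, 0, 0)) {
  new("EggshellSpec", semiAxisX = semiAxisX, semiAxisZ = semiAxisZ,
      yHalfWidth = yHalfWidth, compressed = compressed, center = center)
}

#' Left-right half width of a compressed eggshell
#'
#' Mounting compresses the eggshell by \code{totalCompression} in total
#' along the left-right axis, so the remaining half width is the minor
#' semi-axis minus half the total compression.
#'
#' @param minorSemiAxis uncompressed minor semi-axis, micrometres
#' @param totalCompression total reduction of the left-right diameter
#' @return half width, micrometres
#' @examples
#' halfWidthFromCompression(18.3477, 16.7942)  # 9.9506
#' @export
halfWidthFromCompression <- function(minorSemiAxis, totalCompression) {
  stopifnot(totalCompression >= 0)
  hw <- minorSemiAxis - totalCompression / 2
  if (any(hw <= 0)) stop("compression exceeds the eggshell diameter")
  hw
}

#' Interior volume of a clipped spheroid
#'
#' Volume of the spheroid x^2/a^2 + (y^2 + z^2)/c^2 <= 1 intersected with
#' the slab |y| <= h (closed form from the elliptical cross-section areas).
#'
#' @param spec an \code{EggshellSpec}
#' @return volume, cubic micrometres
#' @export
eggshellVolume <- function(spec) {
  a <- spec@semiAxisX; cc <- spec@semiAxisZ
  h <- if (spec@compressed) min(spec@yHalfWidth, cc) else cc
  pi * a * cc * (2 * h - 2 * h^3 / (3 * cc^2))
}

#' Uncompressed eggshell with equal major axis and volume
#'
#' Solves for the minor semi-axis of an unclipped spheroid that keeps the
#' compressed eggshell's major semi-axis and encloses the same volume.
#'
#' @param compressed a compressed \code{EggshellSpec}
#' @return an uncompressed \code{EggshellSpec}
#' @export
uncompressedSpec <- function(compressed) {
  stopifnot(is(compressed, "EggshellSpec"))
  if (!compressed@compressed)
    stop("spec is already uncompressed")
  v <- eggshellVolume(compressed)
  b <- sqrt(3 * v / (4 * pi * compressed@semiAxisX))
  if (!is.finite(b) || b <= 0) stop("minor semi-axis solve failed")
  EggshellSpec(semiAxisX = compressed@semiAxisX, semiAxisZ = b,
               yHalfWidth = b, compressed = FALSE,
               center = compressed@center)
}

#' Construct the static eggshell boundary field
#'
#' Returns a smooth field that is 0 deep inside the (optionally clipped)
#' spheroid and 1 outside, with a sigmoidal transition of roughly
#' \code{interfaceWidth} voxels centred on the analytic boundary: the 0.5
#' level set lies on the clipped spheroid.  The signed distance to the
#' spheroid is approximated by the normalised implicit function rescaled by
#' its local gradient norm; the clipping planes contribute their exact
#' distance, combined by intersection (max).
#'
#' @param grid a \code{GridSpec}
#' @param spec an \code{EggshellSpec}; must fit in the grid with a margin
#'   of at least 2 voxels
#' @param interfaceWidth transition width, voxels (default 2)
#' @return a \code{\linkS4class{PhaseField}} (the eggshell exterior)
#' @export
eggshellField <- function(grid, spec, interfaceWidth = 2) {
  stopifnot(is(grid, "GridSpec"), is(spec, "EggshellSpec"))
  ax <- gridAxes(grid)
  margin <- 2 * grid@dl
  yext <- if (spec@compressed) spec@yHalfWidth else spec@semiAxisZ
  lo <- spec@center - c(spec@semiAxisX, yext, spec@semiAxisZ)
  hi <- spec@center + c(spec@semiAxisX, yext, spec@semiAxisZ)
  box <- rbind(c(min(ax$x), min(ax$y), min(ax$z)),
               c(max(ax$x), max(ax$y), max(ax$z)))
  if (any(lo < box[1, ] + margin) || any(hi > box[2, ] - margin))
    stop("eggshell does not fit inside the grid with a 2-voxel margin")
  a <- spec@semiAxisX; cc <- spec@semiAxisZ
  xs <- ax$x - spec@center[1]
  ys <- ax$y - spec@center[2]
  zs <- ax$z - spec@center[3]
  d <- array(0, dim = grid@dims)
  # approximate signed distance to the spheroid, slice by slice in z
  xa2 <- (xs / a^2); xn2 <- (xs / a)^2
  for (k in seq_along(zs)) {
    rho2 <- outer(xn2, (ys / cc)^2, "+") + (zs[k] / cc)^2
    rho <- sqrt(rho2)
    gn <- sqrt(outer(xa2^2, (ys / cc^2)^2, "+") + (zs[k] / cc^2)^2)
    len <- rho / pmax(gn, 1e-12)      # local rescale |F|/|grad F|
    len[rho < 1e-9] <- min(a, cc)     # exact centre: depth of the shell
    ds <- (rho - 1) * len
    if (spec@compressed) {
      dp <- abs(ys) - spec@yHalfWidth
      ds <- pmax(ds, matrix(dp, nrow = length(xs), ncol = length(ys),
                            byrow = TRUE))
    }
    d[, , k] <- ds
  }
  w <- interfaceWidth * grid@dl
  new("PhaseField", values = 0.5 * (1 + tanh(d / w)), grid = grid)
}
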