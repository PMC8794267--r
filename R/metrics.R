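#' Voxel label volume of an embryo
#'
#' A voxel belongs to a cell when that cell has the largest phase-field
#' value among all cells there and the value exceeds 0.5; otherwise the
#' voxel is exterior (label 0).  Cells are labelled 1..N in embryo order.
#'
#' @param embryo an \code{EmbryoState}
#' @return integer 3D array of labels
#' @export
labelVolume <- function(embryo) {
  dims <- embryo@grid@dims
  best <- array(0, dim = dims)
  lab <- array(0L, dim = dims)
  for (i in seq_along(embryo@cells)) {
    v <- embryo@cells[[i]]@field@values
    win <- v > best & v > 0.5
    lab[win] <- i
    best <- pmax(best, v)
  }
  lab
}

#' Pairwise contact areas and the contact map
#'
#' Contact area between two cells is the number of voxel faces shared by
#' their labels in the argmax segmentation, times dl^2.  A pair contacts
#' when its area reaches the threshold (default 1 um^2, a few voxel faces
#' at the reference resolution).
#'
#' @param embryo an \code{EmbryoState}
#' @param threshold minimum contact area, um^2
#' @return a \code{\linkS4class{ContactMap}}
#' @export
contactMap <- function(embryo, threshold = 1) {
  nm <- cellNames(embryo)
  lab <- labelVolume(embryo)
  counts <- cpp_face_counts(as.integer(lab), embryo@grid@dims,
                            length(nm) + 1L)
  area <- counts[-1, -1, drop = FALSE] * embryo@grid@dl^2
  idx <- which(upper.tri(area) & area >= threshold, arr.ind = TRUE)
  df <- data.frame(cellA = nm[idx[, 1]], cellB = nm[idx[, 2]],
                   area = area[idx], stringsAsFactors = FALSE)
  new("ContactMap", cells = nm, areas = df[order(df$cellA, df$cellB), ,
                                           drop = FALSE],
      threshold = threshold)
}

#' Contact area between two named cells
#'
#' @param embryo an \code{EmbryoState}
#' @param a,b cell names
#' @return area in um^2 (0 when not contacting)
#' @export
contactArea <- function(embryo, a, b) {
  cm <- contactMap(embryo, threshold = 0)
  hit <- (cm@areas$cellA == a & cm@areas$cellB == b) |
         (cm@areas$cellA == b & cm@areas$cellB == a)
  if (any(hit)) cm@areas$area[hit][1] else 0
}

#' Contacting pairs of a contact map as canonical strings
#'
#' @param cm a \code{ContactMap}
#' @return sorted character vector "A|B" with A < B
#' @export
contactPairs <- function(cm) {
  if (!nrow(cm@areas)) return(character(0))
  a <- pmin(cm@areas$cellA, cm@areas$cellB)
  b <- pmax(cm@areas$cellA, cm@areas$cellB)
  sort(paste(a, b, sep = "|"))
}

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d cells, %d contacting pair(s) (threshold %g um^2)\n",
              length(object@cells), nrow(object@areas), object@threshold))
  if (nrow(object@areas)) print(object@areas, row.names = FALSE)
})

#' Cell surface area
#'
#' The default estimator integrates the gradient norm, sum |grad phi| dl^2,
#' which is exact for a monotone 0-to-1 interface profile; method "ray"
#' cross-checks it by spherical quadrature of the phi = 0.5 isosurface
#' radii around the centre of mass (valid for star-shaped cells).
#'
#' @param cell a \code{CellState}
#' @param method "gradient" (default) or "ray"
#' @param nDirections quadrature directions for method "ray"
#' @return area, um^2
#' @export
surfaceArea <- function(cell, method = c("gradient", "ray"),
                        nDirections = 1000L) {
  method <- match.arg(method)
  f <- cell@field
  if (method == "gradient") {
    gr <- fieldGradient(f)
    sum(sqrt(gr$x^2 + gr$y^2 + gr$z^2)) * f@grid@dl^2
  } else {
    iso <- isosurfaceRadii(f, nDirections = nDirections)
    sum(iso$R^2 / iso$cosGamma) * 4 * pi / nrow(iso)
  }
}

# near-uniform directions on the unit sphere (Fibonacci lattice)
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Radii of the phi = 0.5 isosurface along rays from the centre of mass
#'
#' For each quadrature direction the first outward crossing of the 0.5
#' level is bracketed on a half-voxel march and refined by bisection on the
#' trilinear interpolant; the surface normal (interpolated gradient)
#' provides the obliquity factor cos(gamma) between ray and normal used to
#' convert solid-angle quadrature into surface measure.
#'
#' @param f a \code{PhaseField}
#' @param center ray origin (default: centre of mass)
#' @param nDirections number of directions
#' @return data.frame(R, cosGamma) with one row per direction (um)
#' @export
isosurfaceRadii <- function(f, center = centerOfMass(f), nDirections = 1000L) {
  dirs <- .fibonacciSphere(nDirections)
  dl <- f@grid@dl
  rmax <- max(f@grid@dims) * dl
  if (interpField(f, matrix(center, 1)) < 0.5)
    stop("degenerate isosurface: centre is outside the phi = 0.5 level")
  tstep <- 0.5 * dl
  R <- rep(NA_real_, nDirections)
  alive <- rep(TRUE, nDirections)
  tlo <- rep(0, nDirections)
  t <- tstep
  while (any(alive) && t < rmax) {
    pts <- sweep(dirs[alive, , drop = FALSE] * t, 2, center, "+")
    v <- interpField(f, pts)
    crossed <- v < 0.5
    idx <- which(alive)
    tlo[idx[!crossed]] <- t
    hit <- idx[crossed]
    if (length(hit)) {
      lo <- tlo[hit]; hi <- rep(t, length(hit))
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        pm <- sweep(dirs[hit, , drop = FALSE] * mid, 2, center, "+")
        inside <- interpField(f, pm) >= 0.5
        lo[inside] <- mid[inside]; hi[!inside] <- mid[!inside]
      }
      R[hit] <- (lo + hi) / 2
      alive[hit] <- FALSE
    }
    t <- t + tstep
  }
  if (any(alive)) stop("isosurface ray escaped the grid (non-closed surface?)")
  # obliquity from the interpolated gradient at the crossing points
  pts <- sweep(dirs * R, 2, center, "+")
  eps <- 0.25 * dl
  gx <- (interpField(f, sweep(pts, 2, c(eps, 0, 0), "+")) -
         interpField(f, sweep(pts, 2, c(eps, 0, 0), "-"))) / (2 * eps)
  gy <- (interpField(f, sweep(pts, 2, c(0, eps, 0), "+")) -
         interpField(f, sweep(pts, 2, c(0, eps, 0), "-"))) / (2 * eps)
  gz <- (interpField(f, sweep(pts, 2, c(0, 0, eps), "+")) -
         interpField(f, sweep(pts, 2, c(0, 0, eps), "-"))) / (2 * eps)
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  cosg <- abs(gx * dirs[, 1] + gy * dirs[, 2] + gz * dirs[, 3]) / pmax(gn, 1e-12)
  data.frame(R = R, cosGamma = pmax(cosg, 0.2))
}

#' Deformation coefficient of a cell
#'
#' Dimensionless departure of the cell shape from its equal-volume sphere:
#' alpha = integral over the phi = 0.5 surface of (R - rbar)^2 / (rbar^2
#' R^2) ds, where R is the distance of the surface element to the centre
#' of mass and rbar = (3V / 4 pi)^(1/3) the equivalent-sphere radius from
#' the field volume.  A relaxed sphere gives alpha near 0; alpha is
#' scale-invariant.
#'
#' @param cell a \code{CellState}
#' @param nDirections quadrature directions
#' @return alpha (dimensionless)
#' @export
deformationAlpha <- function(cell, nDirections = 2000L) {
  f <- cell@field
  v <- fieldVolume(f)
  if (v <= 0) stop("degenerate field: zero volume")
  rbar <- (3 * v / (4 * pi))^(1 / 3)
  iso <- isosurfaceRadii(f, nDirections = nDirections)
  ds <- iso$R^2 / iso$cosGamma * 4 * pi / nrow(iso)
  sum((iso$R - rbar)^2 / (rbar^2 * iso$R^2) * ds)
}

#' Average positional variation between simulation and experiment
#'
#' eta = (1/N) sum_i |r_sim,i - r_exp,i|^2, in square micrometres.
#'
#' @param sim,exp N x 3 matrices of matched cell positions (same order)
#' @return eta, um^2
#' @export
positionalVariation <- function(sim, exp) {
  sim <- as.matrix(sim); exp <- as.matrix(exp)
  stopifnot(identical(dim(sim), dim(exp)), ncol(sim) == 3)
  mean(rowSums((sim - exp)^2))
}

#' Absolute relative error between inferred and measured values
#'
#' delta = |s0 - s| / |s| for inferred s0 against measured s.
#'
#' @param inferred simulated value(s) s0
#' @param measured experimental value(s) s (nonzero)
#' @return delta (vectorised)
#' @export
relativeError <- function(inferred, measured) {
  if (any(measured == 0)) stop("measured value must be nonzero")
  abs(inferred / measured - 1)
}

#' Relative-error table for surface and contact areas
#'
#' Joins simulated and measured area tables by name and reports delta per
#' entry plus the average: the comparison used to score an attraction
#' parameterisation against measured 4-cell areas.
#'
#' @param sim,measured data.frames with columns \code{name}, \code{area}
#' @return list(table = per-name delta data.frame, average = mean delta)
#' @export
deltaTable <- function(sim, measured) {
  stopifnot(all(c("name", "area") %in% names(sim)),
            all(c("name", "area") %in% names(measured)))
  m <- merge(sim, measured, by = "name", suffixes = c("_sim", "_exp"))
  if (!nrow(m)) stop("no common names between the two tables")
  m$delta <- relativeError(m$area_sim, m$area_exp)
  list(table = m[order(m$name), ], average = mean(m$delta))
}

#' Classify contacts as conserved across replicate samples
#'
#' A pair contacting in all samples is a conserved contact; in none, a
#' conserved non-contact; otherwise unconserved.
#'
#' @param maps list of \code{ContactMap} over the same cell set (replicate
#'   embryos or repeated runs)
#' @return data.frame(cellA, cellB, nContact, label)
#' @export
classifyConserved <- function(maps) {
  stopifnot(length(maps) >= 1L)
  cells <- sort(maps[[1]]@cells)
  for (m in maps)
    if (!identical(sort(m@cells), cells))
      stop("all maps must cover the same cell set")
  prs <- t(utils::combn(cells, 2))
  key <- paste(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]), sep = "|")
  n <- integer(length(key))
  for (m in maps) n <- n + key %in% contactPairs(m)
  label <- ifelse(n == length(maps), "conserved_contact",
                  ifelse(n == 0L, "conserved_non_contact", "unconserved"))
  data.frame(cellA = prs[, 1], cellB = prs[, 2], nContact = n,
             label = label, stringsAsFactors = FALSE)
}

#' Developmental-path signature of a run
#'
#' The temporal sequence of distinct contact maps: maps sampled along the
#' trajectory with consecutive duplicates (equal contacting pair sets)
#' collapsed.  Two runs follow the same developmental path iff their
#' signatures are equal.
#'
#' @param maps list of \code{ContactMap} in time order
#' @return list of character vectors (canonical pair sets)
#' @export
pathSignature <- function(maps) {
  sig <- list()
  for (m in maps) {
    p <- contactPairs(m)
    if (!length(sig) || !identical(sig[[length(sig)]], p))
      sig[[length(sig) + 1L]] <- p
  }
  sig
}

#' Embryo width along the left-right axis
#'
#' The planarization metric: maximum pairwise distance in y among the cell
#' positions (equivalently max - min).
#'
#' @param positions N x 3 matrix of positions (um), or an
#'   \code{EmbryoState} (centroids are used)
#' @return width, um
#' @export
embryoWidth <- function(positions) {
  if (is(positions, "EmbryoState")) positions <- .centroids(positions)
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0) stop("no positions")
  max(positions[, 2]) - min(positions[, 2])
}

#' Fit the simulation-to-experiment time scale
#'
#' Proportional least-squares fit of per-stage simulated durations (time
#' steps) against experimental durations (minutes) shifted by the fixed
#' intercept deltaT0 — the cytokinesis time between nucleus separation and
#' membrane segregation, which the instantaneous-bisection model does not
#' spend: steps = k (minutes - deltaT0).  R^2 is reported against the mean
#' of the simulated durations.
#'
#' @param simSteps per-stage durations in time steps
#' @param expMinutes matched experimental durations, minutes
#' @param deltaT0 fixed intercept, minutes (default 2.2784)
#' @return a \code{\linkS4class{TimescaleFit}}
#' @export
fitTimescale <- function(simSteps, expMinutes, deltaT0 = 2.2784) {
  stopifnot(length(simSteps) == length(expMinutes))
  if (length(simSteps) < 2) stop("need at least two stages to fit")
  x <- expMinutes - deltaT0
  if (sum(x^2) <= 0) stop("degenerate fit: zero predictor variance")
  k <- sum(x * simSteps) / sum(x^2)
  if (k <= 0) stop("degenerate fit: non-positive slope")
  ss_res <- sum((simSteps - k * x)^2)
  ss_tot <- sum((simSteps - mean(simSteps))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
  new("TimescaleFit", k = k, rSquared = min(r2, 1), deltaT0 = deltaT0)
}

#' Convert simulated steps to in vivo minutes
#'
#' Intervals within a stage need no intercept: minutes = steps / k.
#'
#' @param steps simulated duration, time steps
#' @param fit a \code{TimescaleFit}, or a bare conversion ratio k (time
#'   steps per minute)
#' @return minutes
#' @export
stepsToMinutes <- function(steps, fit) {
  k <- if (is(fit, "TimescaleFit")) fit@k else as.numeric(fit)
  steps / k
}

setMethod("show", "TimescaleFit", function(object) {
  cat(sprintf("TimescaleFit: k = %.4g steps/min (R^2 = %.4f, deltaT0 = %.4f min)\n",
              object@k, object@rSquared, object@deltaT0))
})
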