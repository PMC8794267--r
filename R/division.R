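#' Lineage nomenclature helpers
#'
#' Germline cells are P0..P4; founder cells AB, EMS (and its daughters MS
#' and E), C, D; AB-lineage descendants append a positional suffix (a
#' anterior, p posterior, l left, r right) per generation.
#'
#' @param name a candidate cell name
#' @return \code{isValidCellName}: logical
#' @export
isValidCellName <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) return(FALSE)
  if (grepl("^P[0-4]$", name)) return(TRUE)
  if (name %in% c("EMS", "MS", "E", "C", "D")) return(TRUE)
  if (grepl("^(AB|MS|E|C|D)[aplrdv]+$", name)) return(TRUE)
  identical(name, "AB")
}

#' @rdname isValidCellName
#' @return \code{parentOf}: the parent's name, or NA for the zygote P0
#' @export
parentOf <- function(name) {
  stopifnot(isValidCellName(name))
  special <- c(AB = "P0", P1 = "P0", EMS = "P1", P2 = "P1",
               MS = "EMS", E = "EMS", C = "P2", P3 = "P2",
               D = "P3", P4 = "P3")
  if (name == "P0") return(NA_character_)
  if (name %in% names(special)) return(unname(special[name]))
  # suffixed somatic descendant: drop the last suffix letter
  substr(name, 1L, nchar(name) - 1L)
}

#' @rdname isValidCellName
#' @param a,b two cell names
#' @return \code{areSisters}: TRUE iff the two cells share a parent
#' @export
areSisters <- function(a, b) {
  if (a == b) return(FALSE)
  pa <- parentOf(a); pb <- parentOf(b)
  !is.na(pa) && !is.na(pb) && pa == pb
}

#' Construct a division specification
#'
#' @param mother mother cell name
#' @param daughters character(2); daughters[1] takes the half-space on the
#'   +direction side
#' @param direction 3-vector (normalised internally), or one of the axis
#'   keywords "x"/"ap", "y"/"lr", "z"/"dv"
#' @param ratio positive pair: daughter1 : daughter2 volume ratio
#' @param epsilon split interface width (default 2^-52: a sharp step)
#' @return a \code{\linkS4class{DivisionSpec}}
#' @export
DivisionSpec <- function(mother, daughters, direction, ratio = c(1, 1),
                         epsilon = 2^-52) {
  if (is.character(direction)) {
    direction <- switch(tolower(direction),
      x = , ap = c(1, 0, 0),
      y = , lr = c(0, 1, 0),
      z = , dv = c(0, 0, 1),
      stop("unknown axis keyword: ", direction))
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm <= 0) stop("direction must be nonzero")
  new("DivisionSpec", mother = mother, daughters = daughters,
      direction = direction / nrm, ratio = as.numeric(ratio),
      epsilon = epsilon)
}

# signed distances of all voxels to the plane through `center` (um) with
# unit normal n, in lattice units
.planeDistances <- function(grid, center, n) {
  ax <- gridAxes(grid)
  cx <- (ax$x - center[1]) / grid@dl
  cy <- (ax$y - center[2]) / grid@dl
  cz <- (ax$z - center[3]) / grid@dl
  d <- array(0, dim = grid@dims)
  for (k in seq_along(cz))
    d[, , k] <- outer(n[1] * cx, n[2] * cy, "+") + n[3] * cz[k]
  d
}

# upper-side sigmoid mask of the split plane at offset b
.splitMask <- function(d, b, epsilon) 0.5 * tanh((d - b) / epsilon) + 0.5

#' Plane offset for a prescribed daughter-volume ratio
#'
#' Finds the offset b (lattice units, along the division direction from the
#' mother's centre of mass) minimising the difference between the achieved
#' and prescribed daughter-volume ratio.  The +side daughter volume is
#' monotone non-increasing in b, so a bisection search converges; the
#' search tolerance is 1e-3 voxels.
#'
#' @param field the mother's \code{PhaseField}
#' @param direction unit 3-vector
#' @param ratio positive pair (volume of the +side daughter : other)
#' @param epsilon split interface width
#' @return the offset b, lattice units
#' @export
divisionOffset <- function(field, direction, ratio, epsilon = 2^-52) {
  m <- sum(field@values)
  if (m <= 0) stop("cannot divide a zero-mass field")
  rc <- centerOfMass(field)
  d <- .planeDistances(field@grid, rc, direction)
  target <- m * ratio[1] / sum(ratio)
  v1 <- function(b) sum(field@values * .splitMask(d, b, epsilon))
  lo <- min(d) - 1; hi <- max(d) + 1
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (v1(mid) > target) lo <- mid else hi <- mid
  }
  # with a saturated (step) sigmoid the +side volume is piecewise constant
  # in b and jumps by whole voxel layers; placing the plane exactly on the
  # voxel distance at the jump gives those voxels weight 1/2 and halves
  # the discreteness error, so try that candidate too
  cand <- c(lo, hi, (lo + hi) / 2)
  near <- d[d >= lo - 0.51 & d <= hi + 0.51]
  if (length(near)) cand <- c(cand, unique(near))
  err <- vapply(cand, function(b) abs(v1(b) - target), numeric(1))
  b <- cand[which.min(err)]
  reldev <- abs(v1(b) / target - 1)
  if (reldev > 0.1)
    stop(sprintf("prescribed ratio unreachable: achieved fraction deviates %.1f%%",
                 100 * reldev))
  b
}

#' Divide a cell by instantaneous plane bisection
#'
#' The mother's field is multiplied by complementary sigmoid masks of the
#' signed plane distance (width epsilon), producing two daughter fields
#' that sum to the mother voxelwise.  Daughter prescribed volumes are the
#' mother's prescribed volume split by the achieved mass fractions, so the
#' volume constraint does not fight the split.
#'
#' @param embryo an \code{EmbryoState}
#' @param spec a \code{DivisionSpec}
#' @return the \code{EmbryoState} with the mother replaced by the two
#'   daughters (N + 1 cells)
#' @export
bisectCell <- function(embryo, spec) {
  nm <- cellNames(embryo)
  if (!spec@mother %in% nm)
    stop(sprintf("mother '%s' not present", spec@mother))
  if (any(spec@daughters %in% nm))
    stop("daughter name already present (lineage collision)")
  mother <- getCell(embryo, spec@mother)
  f <- mother@field
  rc <- centerOfMass(f)
  d <- .planeDistances(f@grid, rc, spec@direction)
  b <- divisionOffset(f, spec@direction, spec@ratio, spec@epsilon)
  s1 <- .splitMask(d, b, spec@epsilon)
  s2 <- 0.5 * tanh((b - d) / spec@epsilon) + 0.5
  f1 <- PhaseField(f@values * s1, f@grid)
  f2 <- PhaseField(f@values * s2, f@grid)
  m1 <- sum(f1@values); m2 <- sum(f2@values)
  frac1 <- m1 / (m1 + m2)
  d1 <- CellState(spec@daughters[1], f1, mother@targetVolume * frac1,
                  birthStep = embryo@step)
  d2 <- CellState(spec@daughters[2], f2, mother@targetVolume * (1 - frac1),
                  birthStep = embryo@step)
  keep <- Filter(function(c) c@name != spec@mother, embryo@cells)
  EmbryoState(c(keep, list(d1, d2)), embryo@eggshell, step = embryo@step)
}
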