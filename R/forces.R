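#' Force model parameters
#'
#' @param gamma cell surface tension strength (default 0.25)
#' @param c cortex (interface) thickness coefficient (default 1)
#' @param ge eggshell stiffness (default 16)
#' @param g cell stiffness (default 1.6)
#' @param M volume-constraint strength (default 0.0012)
#' @param gradEps gradient-norm regularisation (default 1e-6)
#' @param maskThresh interface-band mask on |grad phi|^2 (default 1e-8)
#' @param volCap cap on the volume-force magnitude (numerical safeguard
#'   during seeding/inflation; default 4)
#' @return a \code{\linkS4class{ForceParams}}
#' @export
ForceParams <- function(gamma = 0.25, c = 1, ge = 16, g = 1.6, M = 0.0012,
                        gradEps = 1e-6, maskThresh = 1e-8, volCap = 4) {
  new("ForceParams", gamma = gamma, c = c, ge = ge, g = g, M = M,
      gradEps = gradEps, maskThresh = maskThresh, volCap = volCap)
}

#' Double-well potential and its derivative
#'
#' W(phi) = phi^2 (phi - 1)^2 has minima at 0 and 1, the two bulk phases of
#' a cell field.
#'
#' @param phi numeric
#' @return W(phi), or W'(phi) = 2 phi (phi - 1)(2 phi - 1)
#' @export
doubleWell <- function(phi) phi^2 * (phi - 1)^2

#' @rdname doubleWell
#' @export
doubleWellDeriv <- function(phi) 2 * phi * (phi - 1) * (2 * phi - 1)

# interface-band mask + regularised inverse |grad|^2, shared by the force
# line densities; returns list(gr = gradient, g2 = |grad|^2, band = mask)
.gradBand <- function(field, p) {
  gr <- fieldGradient(field)
  g2 <- gr$x^2 + gr$y^2 + gr$z^2
  list(gr = gr, g2 = g2, band = g2 > p@maskThresh)
}

.maskedVec <- function(coef, gr, band) {
  lapply(gr, function(gc) ifelse(band, coef * gc, 0))
}

#' Surface tension force field
#'
#' F_ten = -gamma (lap(phi) - c W'(phi)) grad(phi) / (|grad phi|^2 + eps),
#' masked to the interface band.
#'
#' @param cell a \code{CellState}
#' @param p a \code{ForceParams}
#' @return list of arrays x, y, z
#' @export
surfaceTensionForce <- function(cell, p = ForceParams()) {
  f <- cell@field
  gb <- .gradBand(f, p)
  lap <- fieldValues(fieldLaplacian(f))
  coef <- -p@gamma * (lap - p@c * doubleWellDeriv(f@values)) / (gb$g2 + p@gradEps)
  .maskedVec(coef, gb$gr, gb$band)
}

#' Cell-eggshell and cell-cell repulsion force field
#'
#' F_rep = (ge phi_i phi_e^2 + g phi_i sum_j phi_j^2)
#'         grad(phi_i) / (|grad phi_i|^2 + eps), masked to the interface
#' band.
#'
#' @param cell a \code{CellState}
#' @param others list of the other cells' \code{PhaseField}s
#' @param eggshell the eggshell \code{PhaseField}
#' @param p a \code{ForceParams}
#' @return list of arrays x, y, z
#' @export
repulsionForce <- function(cell, others, eggshell, p = ForceParams()) {
  f <- cell@field
  gb <- .gradBand(f, p)
  s2 <- 0
  for (o in others) s2 <- s2 + fieldValues(o)^2
  coef <- (p@ge * f@values * fieldValues(eggshell)^2 + p@g * f@values * s2) /
    (gb$g2 + p@gradEps)
  .maskedVec(coef, gb$gr, gb$band)
}

#' Cell-cell attraction force field
#'
#' F_atr = sum_j sigma_ij grad(phi_j): an advective pull along the
#' neighbours' interface normals.  Not masked (it is already supported on
#' the neighbours' interfaces) and independent of the cell's own gradient.
#'
#' @param cellName name of the cell the force acts on
#' @param embryo the \code{EmbryoState}
#' @param sigma an \code{AttractionMatrix}
#' @return list of arrays x, y, z
#' @export
attractionForce <- function(cellName, embryo, sigma) {
  out <- NULL
  for (other in embryo@cells) {
    if (other@name == cellName) next
    s <- sigmaBetween(sigma, cellName, other@name)
    if (s == 0) next
    gr <- fieldGradient(other@field)
    if (is.null(out)) out <- lapply(gr, function(gc) s * gc)
    else out <- Map(function(a, gc) a + s * gc, out, gr)
  }
  if (is.null(out)) {
    z <- array(0, dim = embryo@grid@dims)
    out <- list(x = z, y = z, z = z)
  }
  out
}

#' Volume constraint force field
#'
#' Gradient form of the constraint:
#' F_vol = M (int phi - V(t)) grad(phi) / (|grad phi| + eps), masked to the
#' interface band.  The prescribed volume is the cell's
#' \code{targetVolume} converted to lattice units.
#'
#' @param cell a \code{CellState}
#' @param p a \code{ForceParams}
#' @return list of arrays x, y, z
#' @export
volumeForce <- function(cell, p = ForceParams()) {
  f <- cell@field
  gb <- .gradBand(f, p)
  vLat <- cell@targetVolume / f@grid@dl^3
  mv <- p@M * (sum(f@values) - vLat)
  mv <- sign(mv) * min(abs(mv), p@volCap)
  coef <- mv / (sqrt(gb$g2) + p@gradEps)
  .maskedVec(coef, gb$gr, gb$band)
}

#' Net velocity field of one cell
#'
#' u = (F_ten + F_rep + F_atr + F_vol) / tau, voxelwise.
#'
#' @param cellName the cell's name
#' @param embryo the \code{EmbryoState}
#' @param p a \code{ForceParams}
#' @param sigma an \code{AttractionMatrix}
#' @param tau viscosity coefficient
#' @return list of arrays x, y, z
#' @export
netVelocityField <- function(cellName, embryo, p = ForceParams(), sigma,
                             tau = 2.62) {
  cell <- getCell(embryo, cellName)
  others <- lapply(Filter(function(c) c@name != cellName, embryo@cells),
                   function(c) c@field)
  ften <- surfaceTensionForce(cell, p)
  frep <- repulsionForce(cell, others, embryo@eggshell, p)
  fatr <- attractionForce(cellName, embryo, sigma)
  fvol <- volumeForce(cell, p)
  Map(function(a, b, d, e) (a + b + d + e) / tau, ften, frep, fatr, fvol)
}

#' Discrete interface energies of the embryo
#'
#' Surface (Ginzburg-Landau) and repulsive energies summed over cells, in
#' lattice units.  Used to monitor near-variational relaxation when the
#' attraction is off.
#'
#' @param embryo an \code{EmbryoState}
#' @param p a \code{ForceParams}
#' @return list(tension, repulsion, total)
#' @export
embryoEnergy <- function(embryo, p = ForceParams()) {
  eten <- 0; erep <- 0
  egg2 <- fieldValues(embryo@eggshell)^2
  vals <- lapply(embryo@cells, function(c) c@field@values)
  for (i in seq_along(vals)) {
    gr <- fieldGradient(embryo@cells[[i]]@field)
    eten <- eten + p@gamma * sum(0.5 * (gr$x^2 + gr$y^2 + gr$z^2) +
                                   p@c * doubleWell(vals[[i]]))
    s2 <- 0
    for (j in seq_along(vals)) if (j != i) s2 <- s2 + vals[[j]]^2
    erep <- erep + 0.5 * sum(p@ge * vals[[i]]^2 * egg2 + p@g * vals[[i]]^2 * s2)
  }
  list(tension = eten, repulsion = erep, total = eten + erep)
}
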