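#' Binarized attraction levels
#'
#' The fitted attraction strengths: relatively weak (W = 0.2, sister
#' pairs), relatively strong (S = 0.9, non-sister pairs) and especially
#' strong (Sx = 1.6, used by motifs such as a strengthened ABpl-MS
#' contact).
#'
#' @return named numeric vector c(W, S, Sx)
#' @export
attractionLevels <- function() c(W = 0.2, S = 0.9, Sx = 1.6)

#' Construct an attraction matrix with a uniform value
#'
#' @param cells cell names
#' @param value sigma applied to every pair (default 0)
#' @return an \code{\linkS4class{AttractionMatrix}}
#' @export
AttractionMatrix <- function(cells, value = 0) {
  n <- length(cells)
  s <- matrix(value, n, n, dimnames = list(cells, cells))
  diag(s) <- 0
  new("AttractionMatrix", cells = cells, sigma = s)
}

#' Sister-rule attraction matrix
#'
#' Attraction between sister cells is relatively weak (their shared
#' membrane is freshly grown during cytokinesis, before adhesive protein
#' recovers) and between non-sister cells relatively strong.
#'
#' @param cells cell names (lineage-resolvable)
#' @param sigmaW weak level (default 0.2)
#' @param sigmaS strong level (default 0.9)
#' @return an \code{AttractionMatrix}
#' @export
defaultAttractionMatrix <- function(cells, sigmaW = attractionLevels()[["W"]],
                                    sigmaS = attractionLevels()[["S"]]) {
  m <- AttractionMatrix(cells, sigmaS)
  s <- m@sigma
  n <- length(cells)
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (areSisters(cells[i], cells[j])) s[i, j] <- s[j, i] <- sigmaW
  new("AttractionMatrix", cells = cells, sigma = s)
}

#' Fitted 4-cell attraction matrix
#'
#' The optimal combination from the 4-cell area comparison: sigma = 0.9 on
#' ABa-ABp, ABa-EMS, ABp-EMS and ABp-P2, and a weaker sigma = 0.2 on
#' EMS-P2.  The matrix is dense, so the never-contacting ABa-P2 pair also
#' carries the strong value (its force contribution vanishes without field
#' overlap).
#'
#' @param sigmaEMSP2 EMS-P2 value (default 0.2)
#' @param sigma value for all other pairs (default 0.9)
#' @return an \code{AttractionMatrix} over ABa, ABp, EMS, P2
#' @export
fourCellAttractionMatrix <- function(sigmaEMSP2 = attractionLevels()[["W"]],
                                     sigma = attractionLevels()[["S"]]) {
  m <- AttractionMatrix(c("ABa", "ABp", "EMS", "P2"), sigma)
  applyMotif(m, c("EMS", "P2"), sigmaEMSP2)
}

#' Override a single pair (an "attraction motif")
#'
#' @param m an \code{AttractionMatrix}
#' @param pair character(2), the unordered pair
#' @param value new sigma (>= 0)
#' @return a modified copy (the input is unchanged)
#' @export
applyMotif <- function(m, pair, value) {
  stopifnot(is(m, "AttractionMatrix"), length(pair) == 2L, value >= 0)
  if (!all(pair %in% m@cells))
    stop(sprintf("unknown cell(s) in motif: %s",
                 paste(setdiff(pair, m@cells), collapse = ", ")))
  if (pair[1] == pair[2]) stop("motif pair must be two distinct cells")
  s <- m@sigma
  s[pair[1], pair[2]] <- s[pair[2], pair[1]] <- value
  new("AttractionMatrix", cells = m@cells, sigma = s)
}

#' Attraction between two named cells
#'
#' @param m an \code{AttractionMatrix}
#' @param a,b cell names
#' @return sigma(a, b)
#' @export
sigmaBetween <- function(m, a, b) {
  if (!all(c(a, b) %in% m@cells))
    stop("cell name not in attraction matrix")
  m@sigma[a, b]
}

#' Restrict an attraction matrix to a subset of cells
#'
#' @param m an \code{AttractionMatrix}
#' @param cells names to keep (order preserved)
#' @return an \code{AttractionMatrix}
#' @export
subsetAttraction <- function(m, cells) {
  stopifnot(all(cells %in% m@cells))
  new("AttractionMatrix", cells = cells,
      sigma = m@sigma[cells, cells, drop = FALSE])
}

setMethod("show", "AttractionMatrix", function(object) {
  cat(sprintf("AttractionMatrix over %d cells\n", length(object@cells)))
  print(object@sigma)
})
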