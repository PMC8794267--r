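#' Time-integration parameters
#'
#' @param tau viscosity coefficient (default 2.62)
#' @param h explicit Euler time step (default 0.1)
#' @param sampleStride steps between centroid samples (default 100)
#' @param smoothWindow moving-average window in samples (odd, default 21)
#' @param qssMinSeparation minimum sample separation between detected
#'   quasi-steady states (default 20)
#' @param maxSteps per-stage step budget (default 2e5)
#' @return a \code{\linkS4class{DynamicsParams}}
#' @export
DynamicsParams <- function(tau = 2.62, h = 0.1, sampleStride = 100L,
                           smoothWindow = 21L, qssMinSeparation = 20L,
                           maxSteps = 200000L) {
  new("DynamicsParams", tau = tau, h = h,
      sampleStride = as.integer(sampleStride),
      smoothWindow = as.integer(smoothWindow),
      qssMinSeparation = as.integer(qssMinSeparation),
      maxSteps = as.integer(maxSteps))
}

# attraction matrix aligned to the embryo's cell order, as a plain matrix
.sigmaMatrixFor <- function(embryo, sigma) {
  nm <- cellNames(embryo)
  if (is.null(sigma)) return(matrix(0, length(nm), length(nm)))
  subsetAttraction(sigma, nm)@sigma
}

#' Advance the embryo by explicit Euler steps
#'
#' Synchronous advective update
#' phi_i <- phi_i - h u_i . grad(phi_i) for every cell, where u_i is the
#' net force field over the viscosity tau.  Errors out naming the step if
#' a non-finite value is produced (numerical instability).
#'
#' @param embryo an \code{EmbryoState}
#' @param p a \code{ForceParams}
#' @param d a \code{DynamicsParams}
#' @param sigma an \code{AttractionMatrix} (NULL: no attraction)
#' @param nSteps number of steps (default 1)
#' @return the advanced \code{EmbryoState}
#' @export
stepEmbryo <- function(embryo, p = ForceParams(), d = DynamicsParams(),
                       sigma = NULL, nSteps = 1L) {
  sm <- .sigmaMatrixFor(embryo, sigma)
  dims <- embryo@grid@dims
  dl3 <- embryo@grid@dl^3
  res <- cpp_evolve(lapply(embryo@cells, function(c) as.vector(c@field@values)),
                    as.vector(fieldValues(embryo@eggshell)), dims, sm,
                    vapply(embryo@cells, function(c) c@targetVolume / dl3,
                           numeric(1)),
                    p@gamma, p@c, p@ge, p@g, p@M, p@gradEps, p@maskThresh,
                    d@tau, d@h, as.integer(nSteps), p@volCap)
  if (res$bad_step > 0)
    stop(sprintf("numerical instability: non-finite field value at step %d (global step %d)",
                 res$bad_step, embryo@step + res$bad_step))
  cells <- Map(function(cell, f) {
    cell@field <- PhaseField(f, cell@field@grid)
    cell
  }, embryo@cells, res$fields)
  EmbryoState(unname(cells), embryo@eggshell,
              step = embryo@step + as.integer(nSteps))
}

#' Root-mean-square cell velocity from a centroid trace
#'
#' Per-cell speed between consecutive samples is |delta r_c| over the
#' elapsed time (sampleStride x h); the embryo's average velocity is the
#' root mean square over cells, vbar = sqrt(sum v_i^2 / N).
#'
#' @param steps sample steps (length m)
#' @param centroids m x N x 3 array of cell centroids, micrometres
#' @param d a \code{DynamicsParams}
#' @return list(steps, vbar, speeds): speeds is (m-1) x N, vbar length m-1,
#'   both attached to the later sample of each pair
#' @export
averageVelocity <- function(steps, centroids, d = DynamicsParams()) {
  m <- dim(centroids)[1]; n <- dim(centroids)[2]
  if (m < 2) return(list(steps = integer(0), vbar = numeric(0),
                         speeds = matrix(0, 0, n)))
  dt <- diff(steps) * d@h
  disp <- centroids[-1, , , drop = FALSE] - centroids[-m, , , drop = FALSE]
  sp <- sqrt(apply(disp^2, c(1, 2), sum)) / dt
  vbar <- sqrt(rowMeans(sp^2))
  list(steps = steps[-1], vbar = vbar, speeds = sp)
}

#' Detect quasi-steady states in a velocity trace
#'
#' After centred moving-average smoothing, a quasi-steady state is a
#' sample where the first difference of vbar changes sign from negative to
#' positive (a local minimum: zero first derivative, positive second
#' derivative).  Detected minima closer than \code{qssMinSeparation}
#' samples to the previous one are suppressed.
#'
#' @param steps sample steps of the vbar values
#' @param vbar root-mean-square velocity series
#' @param d a \code{DynamicsParams}
#' @return ordered vector of steps at the detected minima (possibly empty)
#' @export
detectQuasiSteady <- function(steps, vbar, d = DynamicsParams()) {
  w <- min(d@smoothWindow, if (length(vbar) %% 2L) length(vbar) else length(vbar) - 1L)
  if (length(vbar) < max(3L, w)) return(integer(0))
  s <- if (w >= 3L)
    as.numeric(stats::filter(vbar, rep(1 / w, w), sides = 2)) else vbar
  ok <- which(!is.na(s))
  s <- s[ok]; st <- steps[ok]
  if (length(s) < 3) return(integer(0))
  dv <- diff(s)
  idx <- which(dv[-length(dv)] < 0 & dv[-1] >= 0) + 1L
  if (!length(idx)) return(integer(0))
  keep <- idx[1]
  for (i in idx[-1])
    if (i - keep[length(keep)] >= d@qssMinSeparation) keep <- c(keep, i)
  st[keep]
}

#' Stop rules for a stage
#'
#' \code{stopFixedSteps(k)} integrates exactly k steps;
#' \code{stopVelocityBelow(eps)} stops at the first sample whose vbar is
#' below eps (micrometres per time unit) — but not while any cell's
#' integrated volume is further than \code{volTol} from its prescribed
#' volume, so that a freshly seeded or freshly divided cell still inflating
#' under the volume constraint (whose centroid barely moves) is not
#' mistaken for mechanical equilibrium; \code{stopQuasiSteady(n)} stops
#' once the n-th quasi-steady state is confirmed.
#'
#' @param k,threshold,n rule parameters
#' @param volTol relative volume mismatch that blocks the velocity rule
#' @return a stop-rule list
#' @export
stopFixedSteps <- function(k) list(type = "fixed_steps", k = as.integer(k))

#' @rdname stopFixedSteps
#' @export
stopVelocityBelow <- function(threshold, volTol = 0.10)
  list(type = "velocity_below", threshold = threshold, volTol = volTol)

#' @rdname stopFixedSteps
#' @export
stopQuasiSteady <- function(n) list(type = "nth_quasi_steady", n = as.integer(n))

# centroids of all cells as an N x 3 matrix
.centroids <- function(embryo) {
  t(vapply(embryo@cells, function(c) centerOfMass(c@field), numeric(3)))
}

#' Integrate one developmental stage until its stop rule fires
#'
#' Runs the embryo forward, sampling cell centroids every
#' \code{sampleStride} steps, and stops per the rule (or at
#' \code{maxSteps}, flagged as a timeout with the trajectory still
#' returned).  For the quasi-steady rule a minimum must be at least half a
#' smoothing window old before it counts as confirmed; the reported stop
#' step is the detected minimum itself, where the embryo is near
#' stationary.
#'
#' @param embryo an \code{EmbryoState}
#' @param p a \code{ForceParams}
#' @param d a \code{DynamicsParams}
#' @param sigma an \code{AttractionMatrix} or NULL
#' @param stop a stop rule (see \code{\link{stopFixedSteps}})
#' @param contactThreshold contact-area threshold (um^2) for the sampled
#'   contact maps; NA disables contact sampling
#' @param metricStride samples between contact-map evaluations (default 5)
#' @return list(embryo, trace, stopStep, timedOut, contactMaps); trace has
#'   steps, centroids (m x N x 3), vbar (aligned to steps[-1])
#' @export
runStage <- function(embryo, p = ForceParams(), d = DynamicsParams(),
                     sigma = NULL, stop = stopFixedSteps(1000L),
                     contactThreshold = NA, metricStride = 5L) {
  startStep <- embryo@step
  nCells <- length(embryo@cells)
  steps <- embryo@step
  cents <- array(NA_real_, dim = c(1L, nCells, 3L))
  cents[1, , ] <- .centroids(embryo)
  cmaps <- list()
  if (!is.na(contactThreshold))
    cmaps[[1]] <- contactMap(embryo, threshold = contactThreshold)
  stopStep <- NA_integer_; timedOut <- FALSE
  budget <- if (stop$type == "fixed_steps") min(stop$k, d@maxSteps) else d@maxSteps
  done <- stop$type == "fixed_steps" && budget == 0L
  while (!done) {
    chunk <- min(d@sampleStride, budget - (embryo@step - startStep))
    if (chunk <= 0L) { timedOut <- stop$type != "fixed_steps"; break }
    embryo <- stepEmbryo(embryo, p, d, sigma, nSteps = chunk)
    steps <- c(steps, embryo@step)
    m <- length(steps)
    cents2 <- array(NA_real_, dim = c(m, nCells, 3L))
    cents2[-m, , ] <- cents; cents2[m, , ] <- .centroids(embryo)
    cents <- cents2
    if (!is.na(contactThreshold) && (m - 1L) %% metricStride == 0L)
      cmaps[[length(cmaps) + 1L]] <- contactMap(embryo,
                                                threshold = contactThreshold)
    av <- averageVelocity(steps, cents, d)
    if (stop$type == "velocity_below") {
      volOK <- all(vapply(embryo@cells, function(c)
        abs(fieldVolume(c@field) / c@targetVolume - 1), numeric(1)) <
          (stop$volTol %||% 0.10))
      hit <- which(av$vbar < stop$threshold)
      if (volOK && length(hit) &&
          av$steps[hit[length(hit)]] == embryo@step) {
        stopStep <- embryo@step; break
      }
    } else if (stop$type == "nth_quasi_steady") {
      qs <- detectQuasiSteady(av$steps, av$vbar, d)
      confirm <- embryo@step - ceiling(d@smoothWindow / 2) * d@sampleStride
      qs <- qs[qs <= confirm]
      if (length(qs) >= stop$n) { stopStep <- qs[stop$n]; break }
    } else if (stop$type == "fixed_steps") {
      if (embryo@step - startStep >= stop$k) { stopStep <- embryo@step; break }
    } else stop("unknown stop rule: ", stop$type)
  }
  if (is.na(stopStep)) { stopStep <- embryo@step; timedOut <- stop$type != "fixed_steps" }
  av <- averageVelocity(steps, cents, d)
  list(embryo = embryo,
       trace = list(steps = steps, centroids = cents, vbar = av$vbar,
                    cells = cellNames(embryo)),
       stopStep = as.integer(stopStep), timedOut = timedOut,
       contactMaps = cmaps)
}

# resolve a stage's attraction policy into an AttractionMatrix (or NULL)
.stageSigma <- function(mode, cells, motifs = list(), value = 0) {
  m <- switch(mode,
    zero = NULL,
    uniform = if (value == 0 || length(cells) < 2L) NULL
              else AttractionMatrix(cells, value),
    fitted4 = {
      full <- fourCellAttractionMatrix()
      present <- intersect(full@cells, cells)
      if (length(present) < 2L) NULL
      else {
        mm <- AttractionMatrix(cells, 0)
        for (a in present) for (b in present)
          if (a != b) mm@sigma[a, b] <- sigmaBetween(full, a, b)
        validObject(mm); mm
      }
    },
    sister_rule = defaultAttractionMatrix(cells),
    stop("unknown attraction mode: ", mode))
  if (!is.null(m))
    for (mo in motifs)
      if (all(mo$pair %in% cells)) m <- applyMotif(m, mo$pair, mo$value)
  m
}

#' Run a multi-stage division program
#'
#' Executes the staged program of a \code{ScenarioConfig}-style list: each
#' stage relaxes under its attraction policy until its stop rule fires,
#' then applies the stage's divisions, refreshes the attraction matrix and
#' continues.  The wild-type program traverses the 1-2-3-4-6-7-8 cell
#' stages (both ABa and ABp divide at the 4-to-6 event).
#'
#' @param embryo the starting \code{EmbryoState}
#' @param program list of stages (elements: attraction, stop, divisions,
#'   optional extraSteps integrated after the stop fires before dividing)
#' @param p a \code{ForceParams}
#' @param d a \code{DynamicsParams}
#' @param contactThreshold contact threshold for path-signature sampling
#' @param verbose print stage progress
#' @return list(embryo, stages, durations, contactMaps, pathSignature)
#' @export
runProgram <- function(embryo, program, p = ForceParams(),
                       d = DynamicsParams(), contactThreshold = 1,
                       verbose = FALSE) {
  stages <- list(); durations <- integer(0); cmaps <- list()
  for (si in seq_along(program)) {
    st <- program[[si]]
    sigma <- .stageSigma(st$attraction$mode, cellNames(embryo),
                         st$attraction$motifs %||% list(),
                         st$attraction$value %||% 0)
    res <- runStage(embryo, p, d, sigma, st$stop,
                    contactThreshold = contactThreshold)
    embryo <- res$embryo
    extra <- st$extraSteps %||% 0L
    if (extra > 0L)
      embryo <- stepEmbryo(embryo, p, d, sigma, nSteps = extra)
    durations <- c(durations, res$stopStep - res$trace$steps[1])
    stages[[si]] <- res
    cmaps <- c(cmaps, res$contactMaps)
    if (verbose)
      message(sprintf("stage %d: %s -> stop at step %d (timedOut=%s)", si,
                      paste(res$trace$cells, collapse = ","),
                      res$stopStep, res$timedOut))
    for (dv in st$divisions %||% list()) embryo <- bisectCell(embryo, dv)
  }
  list(embryo = embryo, stages = stages, durations = durations,
       contactMaps = cmaps,
       pathSignature = if (length(cmaps)) pathSignature(cmaps) else list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
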