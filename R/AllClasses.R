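#' @import methods
NULL

#' Computational lattice specification
#'
#' A regular cuboid voxel lattice. \code{dims} are the voxel counts along the
#' x (anterior-posterior), y (left-right) and z (dorsal-ventral) body axes,
#' \code{dl} the isotropic voxel pitch in micrometres, and \code{origin} the
#' physical coordinate (micrometres) of the centre of voxel (1,1,1).  By
#' default the origin is chosen so the lattice is centred on (0,0,0), which
#' makes mirror symmetries about the eggshell centre exact on the grid.
#'
#' @slot dims integer(3), voxels along x, y, z (all >= 8)
#' @slot dl numeric(1), voxel pitch, micrometres per voxel
#' @slot origin numeric(3), physical coordinate of the first voxel centre
#' @export
setClass("GridSpec",
  representation(dims = "integer", dl = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@dims) != 3L || any(object@dims < 8L))
      msg <- c(msg, "dims must be three integers >= 8")
    if (length(object@dl) != 1L || !is.finite(object@dl) || object@dl <= 0)
      msg <- c(msg, "dl must be a single positive number")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be three finite numbers")
    if (length(msg)) msg else TRUE
  })

#' Eggshell geometry specification
#'
#' The eggshell is a prolate spheroid with major semi-axis \code{semiAxisX}
#' along the anterior-posterior axis and minor semi-axes \code{semiAxisZ}
#' along both left-right and dorsal-ventral axes.  A compressed eggshell
#' (slide-mounted embryo) is additionally clipped by the two planes
#' |y - y_c| = \code{yHalfWidth}.
#'
#' @slot semiAxisX numeric(1), major semi-axis, micrometres
#' @slot semiAxisZ numeric(1), minor semi-axis, micrometres
#' @slot yHalfWidth numeric(1), left-right half width after compression
#' @slot compressed logical(1)
#' @slot center numeric(3), eggshell centre, micrometres
#' @export
setClass("EggshellSpec",
  representation(semiAxisX = "numeric", semiAxisZ = "numeric",
                 yHalfWidth = "numeric", compressed = "logical",
                 center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@semiAxisX >= object@semiAxisZ && object@semiAxisZ > 0))
      msg <- c(msg, "need semiAxisX >= semiAxisZ > 0")
    if (object@compressed && object@yHalfWidth > object@semiAxisZ + 1e-9)
      msg <- c(msg, "yHalfWidth must be <= semiAxisZ when compressed")
    if (object@yHalfWidth <= 0)
      msg <- c(msg, "yHalfWidth must be positive")
    if (length(object@center) != 3L)
      msg <- c(msg, "center must have length 3")
    if (length(msg)) msg else TRUE
  })

#' A diffuse-interface scalar field on a grid
#'
#' Values are nominally in [0, 1]: ~1 inside the phase (cell body, or
#' eggshell exterior), ~0 outside, with a smooth transition layer whose 0.5
#' level set is the interface.  Values are not clamped; transient overshoot
#' is monitored by \code{\link{fieldHealth}} rather than clipped, so that
#' mass bookkeeping and the division-sum identity stay exact.
#'
#' @slot values 3D numeric array matching the grid dims
#' @slot grid a \code{GridSpec}
#' @export
setClass("PhaseField",
  representation(values = "array", grid = "GridSpec"),
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@dims)))
      return("values dims must match grid dims")
    TRUE
  })

#' One cell of the embryo
#'
#' @slot name lineage name (e.g. "ABpl")
#' @slot field the cell's \code{PhaseField}
#' @slot targetVolume prescribed volume, cubic micrometres
#' @slot birthStep simulation step at which the cell appeared
#' @export
setClass("CellState",
  representation(name = "character", field = "PhaseField",
                 targetVolume = "numeric", birthStep = "integer"),
  validity = function(object) {
    msg <- character()
    if (!isValidCellName(object@name))
      msg <- c(msg, sprintf("'%s' is not a valid lineage name", object@name))
    if (object@targetVolume <= 0)
      msg <- c(msg, "targetVolume must be positive")
    if (length(msg)) msg else TRUE
  })

#' The embryo: cells, eggshell, and simulation clock
#'
#' @slot cells list of \code{CellState}
#' @slot eggshell static eggshell \code{PhaseField} (1 outside, 0 inside)
#' @slot grid shared \code{GridSpec}
#' @slot step integer simulation clock, in units of the time step h
#' @export
setClass("EmbryoState",
  representation(cells = "list", eggshell = "PhaseField",
                 grid = "GridSpec", step = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@cells) < 1L || length(object@cells) > 8L)
      msg <- c(msg, "supported scenarios have 1 to 8 cells")
    nm <- vapply(object@cells, function(c) c@name, character(1))
    if (anyDuplicated(nm)) msg <- c(msg, "cell names must be unique")
    ok <- vapply(object@cells, function(c)
      identical(c@field@grid@dims, object@grid@dims), logical(1))
    if (!all(ok)) msg <- c(msg, "all cells must share the embryo grid")
    if (length(msg)) msg else TRUE
  })

#' Force model parameters
#'
#' Defaults are the reference parameterisation of the model: surface tension
#' gamma = 0.25, cortex thickness coefficient c = 1, eggshell stiffness
#' ge = 16, cell stiffness g = 1.6, volume-constraint strength M = 0.0012.
#' \code{gradEps} regularises the gradient-norm denominators where the
#' formal force expressions are 0/0; \code{maskThresh} restricts forces to
#' the interface band (|grad phi|^2 above the threshold), since the force
#' terms are line densities defined on the interface.
#'
#' @slot gamma,c,ge,g,M positive model coefficients (lattice units)
#' @slot gradEps denominator regularisation (default 1e-6)
#' @slot maskThresh interface-band mask on |grad phi|^2 (default 1e-8)
#' @slot volCap cap on the volume-force magnitude M |int phi - V| (lattice
#'   force units, default 1): a numerical safeguard that only engages far
#'   from the operating regime, e.g. while a freshly seeded cell inflates
#' @export
setClass("ForceParams",
  representation(gamma = "numeric", c = "numeric", ge = "numeric",
                 g = "numeric", M = "numeric", gradEps = "numeric",
                 maskThresh = "numeric", volCap = "numeric"),
  validity = function(object) {
    pos <- c(gamma = object@gamma, c = object@c, ge = object@ge,
             g = object@g, M = object@M)
    if (any(pos <= 0)) return("gamma, c, ge, g, M must all be positive")
    if (object@gradEps < 0 || object@maskThresh < 0)
      return("gradEps and maskThresh must be non-negative")
    if (object@volCap <= 0) return("volCap must be positive")
    TRUE
  })

#' Time-integration and event-detection parameters
#'
#' @slot tau viscosity coefficient (default 2.62)
#' @slot h explicit Euler time step (default 0.1)
#' @slot sampleStride steps between centroid samples (default 100)
#' @slot smoothWindow moving-average window, in samples, for the velocity
#'   trace before minimum detection (default 21, odd)
#' @slot qssMinSeparation minimum separation between detected quasi-steady
#'   states, in samples (default 20)
#' @slot maxSteps per-stage integration budget
#' @export
setClass("DynamicsParams",
  representation(tau = "numeric", h = "numeric", sampleStride = "integer",
                 smoothWindow = "integer", qssMinSeparation = "integer",
                 maxSteps = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@tau <= 0 || object@h <= 0)
      msg <- c(msg, "tau and h must be positive")
    if (object@sampleStride < 1L) msg <- c(msg, "sampleStride must be >= 1")
    if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L)
      msg <- c(msg, "smoothWindow must be a positive odd number of samples")
    if (length(msg)) msg else TRUE
  })

#' Symmetric cell-cell attraction matrix
#'
#' Holds the pairwise attraction coefficients sigma(i,j) >= 0.  The model
#' binarizes attraction into a relatively weak level sigma_W = 0.2 (sister
#' pairs) and a relatively strong level sigma_S = 0.9 (non-sister pairs),
#' with an especially strong level sigma'_S = 1.6 available for motifs.
#' The matrix is dense: a value is defined for every unordered pair, and
#' simply contributes no force where the two fields do not overlap.
#'
#' @slot cells character vector of cell names (matrix order)
#' @slot sigma symmetric numeric matrix with zero diagonal
#' @export
setClass("AttractionMatrix",
  representation(cells = "character", sigma = "matrix"),
  validity = function(object) {
    s <- object@sigma
    msg <- character()
    if (!identical(dim(s), rep(length(object@cells), 2L)))
      msg <- c(msg, "sigma must be a square matrix over the cells")
    else {
      if (any(s < 0)) msg <- c(msg, "sigma values must be >= 0")
      if (any(abs(s - t(s)) > 1e-12)) msg <- c(msg, "sigma must be symmetric")
      if (any(diag(s) != 0)) msg <- c(msg, "no self-attraction (diagonal 0)")
    }
    if (length(msg)) msg else TRUE
  })

#' Cell division event specification
#'
#' The mother's field is split instantaneously by the plane
#' n . (r - r_c) - b = 0 through its centre of mass offset by b along the
#' unit direction n.  \code{daughters[1]} receives the half-space on the
#' +n side and the fraction ratio[1]/sum(ratio) of the mother's mass; b is
#' found by a monotone search so the achieved daughter-volume ratio matches
#' the prescribed one.  \code{epsilon} is the width of the interface between
#' the daughters; the default 2^-52 saturates the sigmoid into a sharp
#' {0, 1/2, 1} step mask.
#'
#' @slot mother,daughters cell names (mother present, daughters absent)
#' @slot direction unit 3-vector, the volume segregation direction
#' @slot ratio positive pair, daughter volume ratio (d1 : d2)
#' @slot epsilon split interface width (lattice units)
#' @export
setClass("DivisionSpec",
  representation(mother = "character", daughters = "character",
                 direction = "numeric", ratio = "numeric",
                 epsilon = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@daughters) != 2L)
      msg <- c(msg, "exactly two daughters required")
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
      msg <- c(msg, "direction must be a unit vector")
    if (length(object@ratio) != 2L || any(object@ratio <= 0))
      msg <- c(msg, "ratio must be a positive pair")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
    if (length(msg)) msg else TRUE
  })

#' Cell-cell contact map at one time point
#'
#' Pairs whose voxel-face contact area is at least \code{threshold} (square
#' micrometres) count as contacting.  \code{areas} holds one row per
#' contacting unordered pair.
#'
#' @slot cells all cell names present in the embryo
#' @slot areas data.frame with columns cellA, cellB, area (um^2)
#' @slot threshold minimum contact area, um^2
#' @export
setClass("ContactMap",
  representation(cells = "character", areas = "data.frame",
                 threshold = "numeric"),
  validity = function(object) {
    a <- object@areas
    msg <- character()
    if (!all(c("cellA", "cellB", "area") %in% names(a)))
      msg <- c(msg, "areas needs columns cellA, cellB, area")
    else {
      if (nrow(a) && any(a$area < object@threshold))
        msg <- c(msg, "all listed pairs must have area >= threshold")
      if (nrow(a) && !all(c(a$cellA, a$cellB) %in% object@cells))
        msg <- c(msg, "pair members must be in cells")
    }
    if (length(msg)) msg else TRUE
  })

#' Simulation-to-experiment time-scale fit
#'
#' @slot k conversion ratio, time steps per minute
#' @slot rSquared goodness of fit of the proportional model
#' @slot deltaT0 fixed intercept (minutes): the experimental duration
#'   between nucleus separation and membrane segregation, absent in silico
#' @export
setClass("TimescaleFit",
  representation(k = "numeric", rSquared = "numeric", deltaT0 = "numeric"),
  validity = function(object) {
    if (object@k <= 0) return("k must be positive")
    if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
      return("rSquared must lie in [0, 1]")
    TRUE
  })

#' A fully declarative description of one simulation run
#'
#' @slot name scenario identifier
#' @slot grid,eggshell,params,dynamics geometry and physics
#' @slot volumes named numeric, prescribed cell volumes (um^3) for every
#'   cell that ever exists in the program
#' @slot program list of stages; each stage is a list with elements
#'   \code{attraction} (list: mode, motifs), \code{stop} (a stop rule), and
#'   \code{divisions} (possibly empty list of \code{DivisionSpec}) applied
#'   when the stage ends
#' @slot metrics list of metric settings (contactThreshold, metricStride)
#' @slot provenance named character: which defaults are placeholders rather
#'   than measured values, surfaced in logs so no unsupported number enters
#'   a result silently
#' @export
setClass("ScenarioConfig",
  representation(name = "character", grid = "GridSpec",
                 eggshell = "EggshellSpec", params = "ForceParams",
                 dynamics = "DynamicsParams", volumes = "numeric",
                 program = "list", metrics = "list",
                 provenance = "character"))
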