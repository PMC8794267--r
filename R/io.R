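# serialization of ScenarioConfig to/from plain-list (YAML-stable) form

.divisionToList <- function(d) list(
  mother = d@mother, daughters = as.list(d@daughters),
  direction = as.list(d@direction), ratio = as.list(d@ratio),
  epsilon = d@epsilon)

.divisionFromList <- function(l) DivisionSpec(
  l$mother, unlist(l$daughters), unlist(l$direction), unlist(l$ratio),
  l$epsilon %||% 2^-52)

.stageToList <- function(s) list(
  attraction = list(mode = s$attraction$mode,
                    value = s$attraction$value %||% 0,
                    motifs = lapply(s$attraction$motifs %||% list(),
                                    function(m) list(pair = as.list(m$pair),
                                                     value = m$value))),
  stop = s$stop,
  extra_steps = s$extraSteps %||% 0L,
  divisions = lapply(s$divisions %||% list(), .divisionToList))

.stageFromList <- function(l) list(
  attraction = list(mode = l$attraction$mode,
                    value = l$attraction$value %||% 0,
                    motifs = lapply(l$attraction$motifs %||% list(),
                                    function(m) list(pair = unlist(m$pair),
                                                     value = m$value))),
  stop = {
    s <- l$stop
    if (!is.null(s$k)) s$k <- as.integer(s$k)
    if (!is.null(s$n)) s$n <- as.integer(s$n)
    s
  },
  extraSteps = as.integer(l$extra_steps %||% 0L),
  divisions = lapply(l$divisions %||% list(), .divisionFromList))

#' Convert a scenario configuration to and from a plain list
#'
#' The list form round-trips through YAML (\code{\link{writeScenario}} /
#' \code{\link{loadScenario}}) without loss.
#'
#' @param config a \code{ScenarioConfig}
#' @return \code{scenarioToList}: a nested plain list
#' @export
scenarioToList <- function(config) {
  g <- config@grid; e <- config@eggshell; p <- config@params
  d <- config@dynamics
  list(
    name = config@name,
    grid = list(dims = as.list(g@dims), dl_um = g@dl,
                origin_um = as.list(g@origin)),
    eggshell = list(semi_axis_x_um = e@semiAxisX,
                    semi_axis_z_um = e@semiAxisZ,
                    y_half_width_um = e@yHalfWidth,
                    compressed = e@compressed,
                    center_um = as.list(e@center)),
    params = list(gamma = p@gamma, c = p@c, g_e = p@ge, g = p@g, M = p@M,
                  grad_eps = p@gradEps, mask_thresh = p@maskThresh),
    dynamics = list(tau = d@tau, h = d@h, sample_stride = d@sampleStride,
                    smooth_window = d@smoothWindow,
                    qss_min_separation = d@qssMinSeparation,
                    max_steps = d@maxSteps),
    volumes_um3 = as.list(config@volumes),
    program = lapply(config@program, .stageToList),
    metrics = config@metrics,
    provenance = as.list(config@provenance))
}

#' @rdname scenarioToList
#' @param l a plain list as produced by \code{scenarioToList}
#' @return \code{scenarioFromList}: a validated \code{ScenarioConfig}
#' @export
scenarioFromList <- function(l) {
  need <- c("name", "grid", "eggshell", "params", "dynamics", "volumes_um3",
            "program")
  missing <- setdiff(need, names(l))
  if (length(missing))
    stop("config error: missing required key(s): ",
         paste(missing, collapse = ", "))
  grid <- GridSpec(unlist(l$grid$dims), l$grid$dl_um,
                   origin = unlist(l$grid$origin_um))
  shell <- EggshellSpec(l$eggshell$semi_axis_x_um, l$eggshell$semi_axis_z_um,
                        yHalfWidth = l$eggshell$y_half_width_um,
                        compressed = l$eggshell$compressed,
                        center = unlist(l$eggshell$center_um))
  p <- l$params
  params <- ForceParams(p$gamma, p$c, p$g_e, p$g, p$M,
                        gradEps = p$grad_eps %||% 1e-6,
                        maskThresh = p$mask_thresh %||% 1e-8)
  d <- l$dynamics
  dyn <- DynamicsParams(d$tau, d$h, d$sample_stride %||% 100L,
                        d$smooth_window %||% 21L,
                        d$qss_min_separation %||% 20L,
                        d$max_steps %||% 200000L)
  program <- lapply(l$program, .stageFromList)
  vols <- unlist(l$volumes_um3)
  # lineage validation of every referenced name
  for (st in program) for (dv in st$divisions)
    for (nm in c(dv@mother, dv@daughters))
      if (!isValidCellName(nm))
        stop("config error: invalid lineage name '", nm, "'")
  for (st in program) for (m in st$attraction$motifs)
    for (nm in m$pair)
      if (!isValidCellName(nm))
        stop("config error: invalid lineage name in motif: '", nm, "'")
  .scenario(l$name, grid, shell, program, vols, dynamics = dyn,
            params = params, metrics = l$metrics %||% list(contactThreshold = 1),
            provenance = unlist(l$provenance) %||% character())
}

#' Write / load a scenario configuration as YAML
#'
#' @param config a \code{ScenarioConfig}
#' @param path file path
#' @return \code{loadScenario}: the validated \code{ScenarioConfig};
#'   placeholder provenance entries are surfaced with a message
#' @export
writeScenario <- function(config, path) {
  # full double precision so numeric parameters round-trip exactly
  # (including the 2^-52 division interface width)
  yaml::write_yaml(scenarioToList(config), path,
                   handlers = list(numeric = function(x)
                     structure(sprintf("%.17e", x),
                               class = "verbatim")))
  invisible(path)
}

#' @rdname writeScenario
#' @export
loadScenario <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- scenarioFromList(yaml::read_yaml(path))
  if (length(cfg@provenance))
    message("placeholder defaults in '", cfg@name, "': ",
            paste(names(cfg@provenance), collapse = ", "))
  cfg
}

#' Checkpoint an embryo state to disk
#'
#' Writes the full embryo (all fields, prescribed volumes, clock) so a run
#' can be resumed bit-identically, plus a small YAML manifest with the
#' grid, cell names and step.
#'
#' @param embryo an \code{EmbryoState}
#' @param path checkpoint directory (created)
#' @return invisibly, the path
#' @export
writeCheckpoint <- function(embryo, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(embryo, file.path(path, "embryo.rds"))
  yaml::write_yaml(list(cells = as.list(cellNames(embryo)),
                        step = embryo@step,
                        dims = as.list(embryo@grid@dims),
                        dl_um = embryo@grid@dl),
                   file.path(path, "manifest.yaml"))
  invisible(path)
}

#' @rdname writeCheckpoint
#' @return \code{readCheckpoint}: the restored \code{EmbryoState}
#' @export
readCheckpoint <- function(path) {
  f <- file.path(path, "embryo.rds")
  if (!file.exists(f)) stop("no checkpoint at ", path)
  emb <- readRDS(f)
  validObject(emb)
  emb
}

#' Export the argmax-label segmentation as a TIFF stack
#'
#' One 2D page per z slice; labels are scaled into [0, 1] grey levels
#' (label / N) for viewing in image-analysis tools.  A 2-cell embryo
#' exports exactly 3 distinct values (2 cells + exterior).
#'
#' @param embryo an \code{EmbryoState}
#' @param path output .tif path
#' @return invisibly, the label array
#' @export
exportLabels <- function(embryo, path) {
  lab <- labelVolume(embryo)
  n <- length(embryo@cells)
  pages <- lapply(seq_len(dim(lab)[3]),
                  function(k) t(lab[, , k]) / n)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(lab)
}

#' Tidy metrics report for a finished run
#'
#' Collects per-cell volume, surface area, deformation and centroid plus
#' the contact table into data.frames, and writes them as CSV (and the
#' run summary as JSON) when \code{dir} is given.
#'
#' @param embryo an \code{EmbryoState}
#' @param dir optional output directory for metrics.csv / contacts.csv /
#'   summary.json
#' @param alpha compute the deformation coefficient (ray quadrature;
#'   moderately expensive)
#' @return list(cells, contacts)
#' @export
metricsReport <- function(embryo, dir = NULL, alpha = FALSE) {
  nm <- cellNames(embryo)
  cells <- data.frame(
    cell = nm,
    volume_um3 = vapply(embryo@cells, function(c) fieldVolume(c@field),
                        numeric(1)),
    target_um3 = vapply(embryo@cells, function(c) c@targetVolume, numeric(1)),
    area_um2 = vapply(embryo@cells, surfaceArea, numeric(1)),
    alpha = if (alpha) vapply(embryo@cells, deformationAlpha, numeric(1))
            else NA_real_)
  com <- .centroids(embryo)
  cells$x_um <- com[, 1]; cells$y_um <- com[, 2]; cells$z_um <- com[, 3]
  cm <- contactMap(embryo)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(cm@areas, file.path(dir, "contacts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_cells = length(nm), cells = nm,
           embryo_width_um = embryoWidth(embryo),
           n_contacts = nrow(cm@areas)),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(cells = cells, contacts = cm@areas)
}
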