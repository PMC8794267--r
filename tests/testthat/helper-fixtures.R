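# Shared fixtures, built in code and memoized per test session.  The heavy
# ones (staged embryo runs on coarse grids) are computed once and reused
# across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a single tanh sphere (radius ~15 voxels) relaxed to mechanical
# equilibrium inside a roomy spherical eggshell
relaxedCellFixture <- function() fixture("relaxedCell", function() {
  g <- GridSpec(c(48, 48, 48), 1)
  V <- 4 / 3 * pi * 15^3
  egg <- eggshellField(g, EggshellSpec(21, 20.99, yHalfWidth = 20.99,
                                       compressed = FALSE))
  emb <- EmbryoState(list(CellState("P0", cellSphere(g, c(0, 0, 0), V), V)),
                     egg)
  stepEmbryo(emb, nSteps = 2000L)
})

# symmetric two-cell doublet relaxed under a given uniform attraction
doubletFixture <- function(sigma) fixture(sprintf("doublet_%.1f", sigma),
  function() {
    sc <- builtinScenario("toy_doublet", sigmaValue = sigma, nSteps = 2000L)
    runScenario(sc)
  })

# coarse-grid (gridScale 8) 1-to-4-cell program with the fitted 4-cell
# attraction matrix
fourcellRunFixture <- function() fixture("fourcellRun", function() {
  sc <- builtinScenario("fourcell_emsp2_scan", gridScale = 8)$emsp2_0.2
  runScenario(sc)
})

# coarse-grid full wild-type programs, with and without the ABpl-E motif
wt8MotifFixture <- function() fixture("wt8motif", function() {
  runScenario(builtinScenario("wt_compressed_reduced", gridScale = 8))
})

wt8NoMotifFixture <- function() fixture("wt8nomotif", function() {
  sc <- builtinScenario("wt_compressed_reduced", gridScale = 8)
  sc@program[[7]]$attraction$motifs <- list()
  runScenario(sc)
})

# small two-cell embryo (not relaxed) for force/step consistency checks
twoCellFixture <- function() fixture("twoCell", function() {
  g <- GridSpec(c(30, 30, 30), 1)
  egg <- eggshellField(g, EggshellSpec(12, 11.9, yHalfWidth = 11.9,
                                       compressed = FALSE))
  c1 <- CellState("AB", cellSphere(g, c(-5, 0, 0), 700), 700)
  c2 <- CellState("P1", cellSphere(g, c(5, 1, 1), 600), 620)
  EmbryoState(list(c1, c2), egg)
})

# mirror a 3D array along one axis
mirrorArray <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- dim(a)[axis]:1
  do.call(`[`, c(list(a), idx))
}
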