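test_that("double-well potential has the stated minima and derivative values", {
  expect_equal(doubleWell(0), 0)
  expect_equal(doubleWell(1), 0)
  expect_equal(doubleWell(0.5), 0.0625)
  expect_equal(doubleWellDeriv(0.5), 0)
  expect_equal(doubleWellDeriv(0.25), 0.1875)
  expect_equal(doubleWellDeriv(0.75), -0.1875)
})

test_that("surface tension vanishes on constants and on the stationary 1D profile", {
  g <- GridSpec(c(24, 12, 12), 1)
  p <- ForceParams()
  const <- CellState("P0", PhaseField(array(0.4, dim = g@dims), g), 1)
  ften <- surfaceTensionForce(const, p)
  expect_true(all(unlist(ften) == 0))

  # stationary profile of the Ginzburg-Landau energy: phi = (1+tanh(kx))/2
  # with k = sqrt(c/2); its discrete tension force at interface voxels is
  # small compared to a profile of the wrong width
  ax <- gridAxes(g)
  prof <- function(width) {
    v <- array(rep(0.5 * (1 + tanh(sqrt(p@c / 2) / width * ax$x)), 144),
               dim = g@dims)
    CellState("P0", PhaseField(v, g), 1)
  }
  fStat <- surfaceTensionForce(prof(1), p)
  fWide <- surfaceTensionForce(prof(2), p)
  band <- abs(prof(1)@field@values - 0.5) < 0.45
  expect_lt(max(abs(fStat$x[band])), 0.1 * max(abs(fWide$x)))

  # linearity in gamma
  f2 <- surfaceTensionForce(prof(2), ForceParams(gamma = 0.5))
  expect_equal(f2$x, 2 * fWide$x, tolerance = 1e-12)
})

test_that("repulsion is zero for an isolated cell, linear in g, and reduces overlap", {
  emb <- twoCellFixture()
  p <- ForceParams()
  far <- getCell(emb, "AB")
  none <- repulsionForce(far, list(), PhaseField(array(0, dim = emb@grid@dims),
                                                emb@grid), p)
  expect_true(all(unlist(none) == 0))

  others <- list(getCell(emb, "P1")@field)
  f1 <- repulsionForce(far, others,
                       PhaseField(array(0, dim = emb@grid@dims), emb@grid), p)
  f10 <- repulsionForce(far, others,
                        PhaseField(array(0, dim = emb@grid@dims), emb@grid),
                        ForceParams(g = 16))
  expect_equal(f10$x, 10 * f1$x, tolerance = 1e-12)

  # two overlapping spheres: one explicit step decreases the overlap integral
  g <- GridSpec(c(36, 24, 24), 1)
  egg <- eggshellField(g, EggshellSpec(15, 9, yHalfWidth = 9,
                                       compressed = FALSE))
  c1 <- CellState("AB", cellSphere(g, c(-3, 0, 0), 500), 500)
  c2 <- CellState("P1", cellSphere(g, c(3, 0, 0), 500), 500)
  emb2 <- EmbryoState(list(c1, c2), egg)
  ov0 <- sum(fieldValues(c1@field) * fieldValues(c2@field)^2)
  emb3 <- stepEmbryo(emb2, nSteps = 1L)
  ov1 <- sum(fieldValues(getCell(emb3, "AB")@field) *
             fieldValues(getCell(emb3, "P1")@field)^2)
  expect_lt(ov1, ov0)
})

test_that("attraction is the sigma-weighted sum of neighbour gradients", {
  emb <- twoCellFixture()
  z <- attractionForce("AB", emb, AttractionMatrix(c("AB", "P1"), 0))
  expect_true(all(unlist(z) == 0))
  s <- AttractionMatrix(c("AB", "P1"), 0.9)
  fa <- attractionForce("AB", emb, s)
  gr <- fieldGradient(getCell(emb, "P1")@field)
  expect_equal(fa$x, 0.9 * gr$x, tolerance = 1e-12)
  expect_equal(fa$z, 0.9 * gr$z, tolerance = 1e-12)
})

test_that("volume force vanishes at the prescribed volume and pushes outward on deficit", {
  g <- GridSpec(c(36, 36, 36), 1)
  f <- cellSphere(g, c(0, 0, 0), 3000)
  p <- ForceParams()
  cellAt <- CellState("P0", f, fieldVolume(f))
  fv <- volumeForce(cellAt, p)
  expect_lt(max(abs(unlist(fv))), 1e-12)

  # 10% deficit: force on the +x interface points along +x (outward)
  deflated <- CellState("P0", f, fieldVolume(f) / 0.9)
  fv2 <- volumeForce(deflated, p)
  ix <- which(abs(fieldValues(f)[, 19, 19] - 0.5) < 0.2)
  outer_ix <- ix[ix > 18]
  expect_true(all(fv2$x[cbind(outer_ix, 19, 19)] > 0))

  # a deflated relaxed sphere re-inflates to its prescribed volume
  egg <- eggshellField(g, EggshellSpec(15, 14.9, yHalfWidth = 14.9,
                                       compressed = FALSE))
  emb <- EmbryoState(list(deflated), egg)
  emb <- stepEmbryo(emb, nSteps = 800L)
  # recovers to within the equilibrium offset 2*gamma/(M*R) at which the
  # volume force balances the curvature (Laplace) pressure
  expect_equal(fieldVolume(getCell(emb, "P0")@field),
               deflated@targetVolume, tolerance = 0.02)
})

test_that("net velocity scales inversely with viscosity and sums the four forces", {
  emb <- twoCellFixture()
  s <- AttractionMatrix(c("AB", "P1"), 0.5)
  p <- ForceParams()
  u1 <- netVelocityField("AB", emb, p, s, tau = 2.62)
  u2 <- netVelocityField("AB", emb, p, s, tau = 5.24)
  expect_equal(u1$x, 2 * u2$x, tolerance = 1e-12)

  cell <- getCell(emb, "AB")
  total <- Map(function(a, b, d, e) a + b + d + e,
               surfaceTensionForce(cell, p),
               repulsionForce(cell, list(getCell(emb, "P1")@field),
                              emb@eggshell, p),
               attractionForce("AB", emb, s),
               volumeForce(cell, p))
  expect_equal(u1$y * 2.62, total$y, tolerance = 1e-12)
})

test_that("one kernel step equals the explicit R force composition", {
  emb <- twoCellFixture()
  s <- AttractionMatrix(c("AB", "P1"), 0.9)
  p <- ForceParams(); d <- DynamicsParams()
  emb2 <- stepEmbryo(emb, p, d, s, nSteps = 1L)
  for (nm in c("AB", "P1")) {
    cell <- getCell(emb, nm)
    u <- netVelocityField(nm, emb, p, s, tau = d@tau)
    gr <- fieldGradient(cell@field)
    g2 <- gr$x^2 + gr$y^2 + gr$z^2
    dot <- u$x * gr$x + u$y * gr$y + u$z * gr$z
    dot[g2 <= p@maskThresh] <- 0
    expect_equal(cell@field@values - d@h * dot,
                 getCell(emb2, nm)@field@values, tolerance = 1e-12)
  }
})

test_that("interface energy is non-increasing during relaxation without attraction", {
  emb <- relaxedCellFixture()
  p <- ForceParams()
  e <- embryoEnergy(emb, p)$total
  for (i in 1:5) {
    emb <- stepEmbryo(emb, nSteps = 100L)
    e2 <- embryoEnergy(emb, p)$total
    expect_lt(e2, e + 1e-3 * e)
    e <- e2
  }
})

test_that("forces are local to the support plus stencil halo", {
  emb <- twoCellFixture()
  p <- ForceParams()
  cell <- getCell(emb, "AB")
  f0 <- surfaceTensionForce(cell, p)
  # corrupt voxels far from the cell support
  v <- cell@field@values
  v[28:30, 28:30, 28:30] <- 0.8
  far <- CellState("AB", PhaseField(v, emb@grid), cell@targetVolume)
  f1 <- surfaceTensionForce(far, p)
  sup <- which(cell@field@values > 1e-6, arr.ind = TRUE)
  box <- apply(sup, 2, range)
  i <- (box[1, 1]):(box[2, 1]); j <- (box[1, 2]):(box[2, 2])
  k <- (box[1, 3]):(box[2, 3])
  expect_equal(f0$x[i, j, k], f1$x[i, j, k], tolerance = 1e-14)
})
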