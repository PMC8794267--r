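test_that("lineage nomenclature resolves parents and sisters", {
  expect_equal(parentOf("AB"), "P0")
  expect_equal(parentOf("P2"), "P1")
  expect_equal(parentOf("MS"), "EMS")
  expect_equal(parentOf("ABpl"), "ABp")
  expect_equal(parentOf("ABalr"), "ABal")
  expect_true(is.na(parentOf("P0")))
  expect_true(areSisters("ABa", "ABp"))
  expect_true(areSisters("EMS", "P2"))
  expect_true(areSisters("C", "P3"))
  expect_false(areSisters("ABpl", "E"))
  expect_false(areSisters("ABa", "ABa"))
  expect_false(isValidCellName("XYZ"))
})

test_that("the wild-type program yields the canonical 8-cell name set", {
  nm <- c("P0")
  divs <- list(c("P0", "AB", "P1"), c("AB", "ABa", "ABp"),
               c("P1", "EMS", "P2"), c("ABa", "ABal", "ABar"),
               c("ABp", "ABpl", "ABpr"), c("EMS", "MS", "E"),
               c("P2", "C", "P3"))
  for (d in divs) nm <- c(setdiff(nm, d[1]), d[2:3])
  expect_setequal(nm, c("ABal", "ABar", "ABpl", "ABpr", "MS", "E", "C", "P3"))
  for (d in divs) expect_true(areSisters(d[2], d[3]))
})

test_that("plane offset hits prescribed ratios and is antisymmetric", {
  g <- GridSpec(c(40, 40, 40), 1)
  f <- cellSphere(g, c(0, 0, 0), 8000)
  # symmetric split through the centre of mass
  b0 <- divisionOffset(f, c(1, 0, 0), c(1, 1))
  expect_lt(abs(b0), 1)
  # 2:1 split vs an exhaustive offset scan (independent oracle)
  dirA <- c(1, 0, 0)
  rc <- centerOfMass(f)
  ax <- gridAxes(g)
  d <- array(rep((ax$x - rc[1]) / g@dl, times = 1600), dim = g@dims)
  m <- sum(f@values)
  target <- m * 2 / 3
  vb <- function(b) sum(f@values * (0.5 * tanh((d - b) / 2^-52) + 0.5))
  bs <- seq(-16, 16, by = 0.02)
  errs <- vapply(bs, function(b) abs(vb(b) - target), numeric(1))
  bestErr <- min(errs)
  b21 <- divisionOffset(f, dirA, c(2, 1))
  expect_lte(abs(vb(b21) - target), bestErr + 1e-9)
  # antisymmetry under direction reversal for an asymmetric ratio
  bneg <- divisionOffset(f, -dirA, c(1, 2))
  expect_equal(bneg, -b21, tolerance = 0.51)  # within the snap discreteness
})

test_that("bisection partitions the mother exactly and splits prescribed volumes", {
  g <- GridSpec(c(40, 40, 40), 1)
  egg <- eggshellField(g, EggshellSpec(17, 16.9, yHalfWidth = 16.9,
                                       compressed = FALSE))
  mother <- CellState("P2", cellSphere(g, c(0, 0, 0), 8000), 8000)
  emb <- EmbryoState(list(mother), egg)
  # oblique direction spreads plane distances finely over the lattice
  n <- c(1, 0.37, 0.21); n <- n / sqrt(sum(n^2))
  spec <- DivisionSpec("P2", c("C", "P3"), n, ratio = c(2, 1))
  emb2 <- bisectCell(emb, spec)
  expect_setequal(cellNames(emb2), c("C", "P3"))
  vc <- getCell(emb2, "C"); vp <- getCell(emb2, "P3")
  # exact voxelwise mass partition at the default (step) epsilon
  expect_equal(vc@field@values + vp@field@values, mother@field@values,
               tolerance = 1e-14)
  # achieved mass ratio within 0.5% of 2:1 on an obliquely cut sphere
  expect_equal(sum(vc@field@values) / sum(vp@field@values), 2,
               tolerance = 0.005)
  # prescribed volumes split by the achieved fraction, conserving the total
  expect_equal(vc@targetVolume + vp@targetVolume, 8000)
  expect_equal(vc@targetVolume / vp@targetVolume, 2, tolerance = 0.005)
  # daughters also partition mass exactly for a finite split width
  spec2 <- DivisionSpec("P2", c("C", "P3"), n, ratio = c(2, 1), epsilon = 2)
  emb3 <- bisectCell(emb, spec2)
  expect_equal(getCell(emb3, "C")@field@values +
               getCell(emb3, "P3")@field@values,
               mother@field@values, tolerance = 1e-12)
  # larger daughter sits on the + side of the division direction
  expect_gt(sum((centerOfMass(vc@field) - centerOfMass(vp@field)) * n), 0)
})

test_that("the step-mask split takes only the values 0, 1/2 and 1", {
  g <- GridSpec(c(24, 24, 24), 1)
  f <- cellSphere(g, c(0, 0, 0), 1500)
  b <- divisionOffset(f, c(0, 0, 1), c(1, 1))
  ax <- gridAxes(g)
  d <- aperm(array(rep(ax$z / g@dl, times = 576), dim = c(24, 24, 24)),
             c(2, 3, 1))
  s <- 0.5 * tanh((d - b) / 2^-52) + 0.5
  expect_true(all(s %in% c(0, 0.5, 1)))
})

test_that("division on a relaxed non-spherical cell keeps ratio fidelity", {
  res <- fourcellRunFixture()
  emb <- res$embryo
  ems <- getCell(emb, "EMS")
  n <- c(0.9, 0.31, 0.29); n <- n / sqrt(sum(n^2))
  b <- divisionOffset(ems@field, n, c(1, 1))
  d <- embryophase:::.planeDistances(emb@grid, centerOfMass(ems@field), n)
  v1 <- sum(ems@field@values * (0.5 * tanh((d - b) / 2^-52) + 0.5))
  expect_equal(v1 / sum(ems@field@values), 0.5, tolerance = 0.005)
})

test_that("name collisions and missing mothers are lineage errors", {
  g <- GridSpec(c(24, 24, 24), 1)
  egg <- eggshellField(g, EggshellSpec(9, 8.9, yHalfWidth = 8.9,
                                       compressed = FALSE))
  emb <- EmbryoState(list(CellState("AB", cellSphere(g, c(0, 0, 0), 900),
                                    900)), egg)
  expect_error(bisectCell(emb, DivisionSpec("P1", c("EMS", "P2"), "x")),
               "not present")
  expect_error(bisectCell(emb, DivisionSpec("AB", c("AB", "ABp"), "x")),
               "collision")
})
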