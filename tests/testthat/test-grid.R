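test_that("compression half-width arithmetic is exact", {
  expect_equal(halfWidthFromCompression(18.3477, 16.7942), 9.9506)
  expect_equal(halfWidthFromCompression(18.3477, 0), 18.3477)
  r <- 7.3; eps <- 1e-4
  expect_equal(halfWidthFromCompression(r, 2 * r - eps), eps / 2)
  expect_error(halfWidthFromCompression(5, 10.5), "exceeds")
})

test_that("eggshell field is 0 inside, 1 outside, 0.5 on the boundary", {
  g <- GridSpec(c(64, 32, 64), 1.0032)
  sp <- EggshellSpec(27.5837, 18.3477, yHalfWidth = 9.9506, compressed = TRUE)
  egg <- eggshellField(g, sp)
  v <- fieldValues(egg)
  expect_lt(interpField(egg, c(0, 0, 0)), 0.02)
  expect_gt(v[1, 1, 1], 0.999)
  expect_equal(interpField(egg, c(27.5837, 0, 0)), 0.5, tolerance = 0.2)
  expect_equal(interpField(egg, c(0, 9.9506, 0)), 0.5, tolerance = 0.2)
  expect_equal(interpField(egg, c(0, 0, -18.3477)), 0.5, tolerance = 0.2)
})

test_that("the 0.5 level set tracks the analytic clipped spheroid within a voxel", {
  g <- GridSpec(c(64, 32, 64), 1.0032)
  sp <- EggshellSpec(27.5837, 18.3477, yHalfWidth = 9.9506, compressed = TRUE)
  egg <- eggshellField(g, sp)
  set.seed(7)
  n <- 1000
  # sample analytic surface points: spheroid patch kept after clipping,
  # plus points on the clipping planes inside the spheroid ellipse
  th <- runif(n, 0, 2 * pi); u <- runif(n, -1, 1)
  pts <- cbind(27.5837 * u,
               18.3477 * sqrt(1 - u^2) * cos(th),
               18.3477 * sqrt(1 - u^2) * sin(th))
  onSpheroid <- abs(pts[, 2]) <= 9.9506
  pts2 <- pts[!onSpheroid, , drop = FALSE]
  pts2[, 2] <- sign(pts2[, 2]) * 9.9506   # project clipped points onto planes
  # keep plane points strictly inside the spheroid cross-section
  keep <- (pts2[, 1] / 27.5837)^2 + (9.9506 / 18.3477)^2 +
    (pts2[, 3] / 18.3477)^2 < 1
  surf <- rbind(pts[onSpheroid, ], pts2[keep, ])
  vals <- interpField(egg, surf)
  # phi at the analytic surface must be within the one-voxel band of 0.5
  # (field value at distance 1 voxel from the levelset: tanh(1/2) ~ 0.73)
  expect_true(all(vals > 0.5 - 0.24 & vals < 0.5 + 0.24))
})

test_that("eggshell interior volume matches the closed form within 1% at reference resolution", {
  g <- GridSpec(c(256L, 128L, 256L), 0.2508)
  sp <- EggshellSpec(27.5837, 18.3477, yHalfWidth = 9.9506, compressed = TRUE)
  egg <- eggshellField(g, sp)
  vox <- sum(fieldValues(egg) < 0.5) * g@dl^3
  expect_equal(vox, eggshellVolume(sp), tolerance = 0.01)
})

test_that("eggshell field has exact mirror symmetries on a centred grid", {
  g <- GridSpec(c(34, 16, 34), 2.0064)
  sp <- EggshellSpec(27.5837, 18.3477, yHalfWidth = 9.9506, compressed = TRUE)
  v <- fieldValues(eggshellField(g, sp))
  for (ax in 1:3) expect_identical(v, mirrorArray(v, ax))
})

test_that("eggshell exceeding the grid is a geometry error", {
  g <- GridSpec(c(16, 16, 16), 1)
  expect_error(eggshellField(g, EggshellSpec(20, 10)), "fit")
})

test_that("uncompressed spec preserves major axis and volume", {
  comp <- EggshellSpec(27.5837, 18.3477, yHalfWidth = 9.9506,
                       compressed = TRUE)
  un <- uncompressedSpec(comp)
  expect_false(un@compressed)
  expect_equal(un@semiAxisX, comp@semiAxisX)
  expect_equal(eggshellVolume(un), eggshellVolume(comp), tolerance = 0.005)
  # identity when the clipping planes touch the spheroid
  noclip <- EggshellSpec(20, 15, yHalfWidth = 15, compressed = TRUE)
  expect_equal(uncompressedSpec(noclip)@semiAxisZ, 15, tolerance = 1e-6)
})

test_that("closed-form clipped volume agrees with a voxel-count oracle", {
  sp <- EggshellSpec(27.5837, 18.3477, yHalfWidth = 9.9506, compressed = TRUE)
  # independent voxel-count oracle on a fine grid over the bounding box
  d <- 0.25
  xs <- seq(-28, 28, by = d); ys <- seq(-10.2, 10.2, by = d)
  zs <- seq(-18.6, 18.6, by = d)
  cnt <- 0
  for (z in zs) {
    inside <- outer((xs / 27.5837)^2, (ys / 18.3477)^2, "+") +
      (z / 18.3477)^2 < 1
    inside <- inside & matrix(abs(ys) <= 9.9506, nrow = length(xs),
                              ncol = length(ys), byrow = TRUE)
    cnt <- cnt + sum(inside)
  }
  expect_equal(cnt * d^3, eggshellVolume(sp), tolerance = 0.005)
})
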