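test_that("structured meshing counts, votes and angle assignment", {
  m <- meshFromLabels(labelImage(matrix(0L, 2, 2), 5), constantAngleDeg = 30)
  expect_equal(m@nx * m@ny, 4L)
  expect_equal(periodicCouplings(m)@nNodes, 9L)
  expect_true(all(m@elemAngleDeg == 30))

  ## majority vote with the stroma > epithelium > lumen tie rule
  r <- matrix(c(0L, 1L, 1L, 1L,    # block (ex=0,ey=0): 0,1,1,1 -> 1
                2L, 2L, 0L, 0L,    # block (ex=1,ey=0): tie 2/0 -> 0
                1L, 1L, 2L, 2L,    # block (ex=0,ey=1): tie 1/2 -> 1
                2L, 2L, 2L, 0L),   # block (ex=1,ey=1): -> 2
              4, 4)
  ## assemble the raster explicitly: rows = y, cols = x
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- c(0L, 1L, 1L, 1L)
  lab[1:2, 3:4] <- c(2L, 2L, 0L, 0L)
  lab[3:4, 1:2] <- c(1L, 1L, 2L, 2L)
  lab[3:4, 3:4] <- c(2L, 2L, 2L, 0L)
  m2 <- meshFromLabels(labelImage(lab, 1), coarsen = 2,
                       constantAngleDeg = 0)
  expect_identical(m2@elemLabel, c(1L, 0L, 1L, 2L))
  expect_error(meshFromLabels(labelImage(matrix(0L, 4, 4), 1), coarsen = 3),
               "divide")
})

test_that("periodic couplings pair every boundary node exactly once", {
  m <- meshFromLabels(labelImage(matrix(0L, 2, 2), 5), constantAngleDeg = 0)
  pc <- periodicCouplings(m)
  ## 3x3 node grid: 1 right-edge pair, 1 top-edge pair, 3 corner ties
  expect_equal(nrow(pc@pairs), 5L)
  boundary <- as.integer(c(1:3, 4, 6, 7:9))
  covered <- sort(unique(c(pc@pairs$slave, pc@pairs$master, pc@pinned)))
  expect_identical(covered, sort(boundary))
  expect_false(anyDuplicated(pc@pairs$slave) > 0)
  expect_true(all(!pc@pairs$master %in% pc@pairs$slave))
})

test_that("a homogeneous cell under macro strain deforms affinely", {
  mod <- homogeneousModel(4, angleDeg = 0)
  r <- solveLoadCase(mod, neoHookean(10), macroLoadCase("uniaxial-1", 1))
  H <- r$Hbar
  n <- 5
  ux <- matrix(r$u[seq(1, length(r$u), 2)], n, n, byrow = TRUE)
  X <- outer(rep(1, n), 0:4) * 10
  Y <- outer(0:4, rep(1, n)) * 10
  expect_lt(max(abs(ux - (H[1] * X + H[3] * Y))), 1e-9)
  uy <- matrix(r$u[seq(2, length(r$u), 2)], n, n, byrow = TRUE)
  expect_lt(max(abs(uy - (H[4] * X + H[2] * Y))), 1e-9)
})

test_that("zero-magnitude loading returns zero displacement and stress", {
  mod <- homogeneousModel(4)
  r <- solveLoadCase(mod, neoHookean(5), macroLoadCase("uniaxial-1", 1, 0))
  expect_equal(max(abs(r$u)), 0)
  expect_equal(max(abs(r$sigmaAvg)), 0)
})

test_that("homogeneous-cell homogenization reproduces the pointwise
           plane-stress response for all six cases (NH and HGO)", {
  mod <- homogeneousModel(8, angleDeg = 20)
  cases <- expand.grid(kind = c("uniaxial-1", "uniaxial-2", "shear-12"),
                       sign = c(1, -1), stringsAsFactors = FALSE)
  for (mat in list(neoHookean(12), hgo(17.5, 155, 200, 0))) {
    ang <- if (is(mat, "HGO")) 20 else NA
    for (k in seq_len(nrow(cases))) {
      r <- solveLoadCase(mod, mat,
                         macroLoadCase(cases$kind[k], cases$sign[k], 0.05))
      pt <- pointMacroResponse(mat, cases$kind[k], cases$sign[k], 0.05,
                               fiberAngleDeg = ang)
      comp <- switch(cases$kind[k], "uniaxial-1" = 1, "uniaxial-2" = 2,
                     "shear-12" = 3)
      ref <- c(pt$sigma[1, 1], pt$sigma[2, 2], pt$sigma[1, 2])[comp]
      expect_equal(r$sigmaAvg[comp], ref, tolerance = 5e-3)
      expect_lt(r$hillMandel, 1e-8)
    }
  }
})

test_that("fibre rotation by 90 degrees swaps E11 and E22", {
  mat <- hgo(10, 60, 80, 0)
  m0 <- homogeneousModel(4, angleDeg = 0)
  m90 <- homogeneousModel(4, angleDeg = 90)
  a <- apparentModuli(solveAllCases(m0, mat))
  b <- apparentModuli(solveAllCases(m90, mat))
  expect_equal(a@E11t, b@E22t, tolerance = 0.01)
  expect_equal(a@E22c, b@E11c, tolerance = 0.01)
  expect_equal(a@G12t, b@G12t, tolerance = 0.01)
})

test_that("kappa = 1/3 apparent moduli are isotropic in the fibre angle", {
  mat <- hgo(10, 60, 80, 1 / 3)
  m <- homogeneousModel(4, angleDeg = 37)
  am <- apparentModuli(solveAllCases(m, mat))
  expect_equal(am@E11t, am@E22t, tolerance = 5e-3)
  expect_equal(am@E11c, am@E22c, tolerance = 5e-3)
})

test_that("compressive moduli along the fibre are k1-independent", {
  m <- homogeneousModel(4, angleDeg = 0)
  cs <- vapply(c(10, 155, 300), function(k1) {
    r <- solveLoadCase(m, hgo(17.5, k1, 200, 0),
                       macroLoadCase("uniaxial-1", -1))
    abs(r$sigmaAvg[1]) / 0.05
  }, numeric(1))
  expect_lt(max(cs) - min(cs), 1e-9 * cs[1])
})

test_that("apparent moduli are monotone in any phase's C10", {
  g <- generateMicrostructure(microstructureSpec(widthPx = 32,
                                                 heightPx = 32,
                                                 pixelSizeUm = 16,
                                                 nAcini = 3,
                                                 lumenRadiusMeanUm = 50,
                                                 lumenRadiusSdUm = 8,
                                                 epitheliumThicknessUm = 35,
                                                 elongation = 1,
                                                 seed = 21))
  rve <- mirrorOrthotropic(g$label,
                           generateFiberField(g$label, "constant", 0))
  mod <- meshFromLabels(rve)
  e11 <- vapply(c(5, 17.5, 30), function(c10) {
    mats <- list(stroma = hgo(c10, 155, 200, 0),
                 epithelium = neoHookean(0.96), lumen = neoHookean(19.2))
    r <- solveLoadCase(mod, mats, macroLoadCase("uniaxial-1", 1))
    r$sigmaAvg[1] / 0.05
  }, numeric(1))
  expect_true(all(diff(e11) > 0))
})

test_that("secant modulus at small strain approaches 6*C10 as nu -> 0.5", {
  C10 <- 11
  m <- homogeneousModel(2)
  r <- solveLoadCase(m, neoHookean(C10, nu = 0.4999),
                     macroLoadCase("uniaxial-1", 1, 0.005))
  E <- r$sigmaAvg[1] / 0.005
  expect_equal(E, 6 * C10, tolerance = 0.02)
})

test_that("missing cases are reported by apparentModuli", {
  expect_error(apparentModuli(list(`uni1+` = NULL)), "missing case")
})

test_that("convergence study: a homogeneous image converges immediately", {
  lab <- labelImage(matrix(0L, 64, 64), 10)
  sizes <- c(160, 320, 480)
  tab <- rveConvergenceStudy(lab, sizes, materials = neoHookean(10),
                             coarsen = c(1, 2, 3))
  expect_equal(nrow(tab), 3L)
  expect_false(any(tab$failed))
  expect_equal(attr(tab, "convergedSizeUm"), 160)
  expect_lt(max(abs(tab$E11t - tab$E11t[1])), 1e-6 * tab$E11t[1])
})

test_that("the fully prescribed macro-strain variant constrains the
           transverse response", {
  mod <- homogeneousModel(2)
  m <- neoHookean(10, nu = 0.49)
  free <- solveLoadCase(mod, m, macroLoadCase("uniaxial-1", 1),
                        transverse = "free")
  fixed <- solveLoadCase(mod, m, macroLoadCase("uniaxial-1", 1),
                         transverse = "fixed")
  ## suppressing lateral contraction stiffens the response and leaves a
  ## transverse normal stress behind
  expect_gt(fixed$sigmaAvg[1], free$sigmaAvg[1])
  expect_gt(abs(fixed$sigmaAvg[2]), 1e-3)
  expect_lt(abs(free$sigmaAvg[2]), 1e-8)
  expect_equal(fixed$Hbar[2], 0)
})
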