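test_that("rotating by zero is a centred crop with unchanged angles", {
  g <- generateMicrostructure(microstructureSpec(widthPx = 64,
                                                 heightPx = 64,
                                                 nAcini = 2,
                                                 lumenRadiusMeanUm = 20,
                                                 lumenRadiusSdUm = 3,
                                                 epitheliumThicknessUm = 20,
                                                 seed = 8))
  ff <- generateFiberField(g$label, "constant", angleDeg = 20)
  rc <- rotateAndCrop(g$label, ff, angleDeg = 0, outSizePx = 32)
  expect_identical(labels(rc$label), labels(g$label)[17:48, 17:48])
  a <- angles(rc$orientation)
  expect_true(all(a[!is.na(a)] == 20))
})

test_that("90-degree rotations are exact raster rotations", {
  g <- generateMicrostructure(microstructureSpec(widthPx = 48,
                                                 heightPx = 48,
                                                 nAcini = 2,
                                                 lumenRadiusMeanUm = 15,
                                                 lumenRadiusSdUm = 3,
                                                 epitheliumThicknessUm = 12,
                                                 seed = 9))
  rc <- rotateAndCrop(g$label, angleDeg = -90, outSizePx = 48)
  expect_identical(labels(rc$label),
                   HistoMech:::rot90Raster(labels(g$label), 1L))
})

test_that("rotating stripes by their angle makes them horizontal", {
  lab <- stripeLabel(30, W = 128, half = 8)
  ff <- generateFiberField(lab, "constant", angleDeg = 30)
  rc <- rotateAndCrop(lab, ff, angleDeg = 30, outSizePx = 80)
  om <- localOrientationMap(rc$label, windowPx = 16)
  a <- angles(om)
  expect_lt(median(axialDiff(a[!is.na(a)], 0)), 2)
  ## carried fibre angles were decremented to ~0
  ca <- angles(rc$orientation)
  expect_true(all(axialDiff(ca[!is.na(ca)], 0) < 1e-9))
})

test_that("an oversized crop reports the maximal admissible size", {
  lab <- stripeLabel(30, W = 64, half = 8)
  expect_error(rotateAndCrop(lab, angleDeg = 30, outSizePx = 60),
               "maximal admissible size is [0-9]+ px")
})

test_that("alignment verification flags deliberate mis-rotation", {
  g <- generateMicrostructure(alignmentSpec(3))
  fr <- fabricAnalysis(g$label, phase = "lumen", seed = 3)
  pa <- as.numeric(principalAngle(fr@fit))
  good <- rotateAndCrop(g$label, angleDeg = pa, outSizePx = 170)
  devG <- verifyPrincipalAlignment(good$label, phase = "lumen", seed = 31)
  expect_lte(as.numeric(devG), 2)
  expect_true(attr(devG, "pass"))
  bad <- rotateAndCrop(g$label, angleDeg = pa + 10, outSizePx = 170)
  devB <- verifyPrincipalAlignment(bad$label, phase = "lumen", seed = 31)
  expect_false(attr(devB, "pass"))
  expect_lt(abs(as.numeric(devB) - 10), 3)
})

test_that("near-isotropic fabric passes alignment with a note", {
  m <- matrix(0L, 101, 101)
  m[diskMask(101, 30)] <- 2L           # circle-only lumen fabric
  dev <- verifyPrincipalAlignment(labelImage(m, 1), phase = "lumen",
                                  seed = 1)
  expect_true(attr(dev, "pass"))
  expect_match(attr(dev, "note"), "isotropic")
})

test_that("mirroring yields exact periodicity, symmetry and fractions", {
  g <- generateMicrostructure(microstructureSpec(widthPx = 48,
                                                 heightPx = 48,
                                                 nAcini = 2,
                                                 lumenRadiusMeanUm = 15,
                                                 lumenRadiusSdUm = 3,
                                                 epitheliumThicknessUm = 12,
                                                 seed = 10))
  ff <- generateFiberField(g$label, "constant", angleDeg = 30)
  rve <- mirrorOrthotropic(g$label, ff)
  m <- labels(rve)
  expect_identical(dim(m), c(96L, 96L))
  rep <- verifyPeriodicity(rve@labels)
  expect_true(rep$ok)
  ## mirror symmetry about centre lines
  expect_identical(m, m[, ncol(m):1])
  expect_identical(m, m[nrow(m):1, ])
  expect_identical(areaFractions(rve@labels), areaFractions(g$label))
  ## axial angles reflect as theta -> -theta in the single-flip quadrants
  A <- angles(rve@orientation)
  q <- function(i, j) A[i, j]
  expect_true(all(q(1:48, 1:48) == 30, na.rm = TRUE))
  expect_true(all(q(1:48, 49:96) == -30, na.rm = TRUE))
  expect_true(all(q(49:96, 1:48) == -30, na.rm = TRUE))
  expect_true(all(q(49:96, 49:96) == 30, na.rm = TRUE))
})

test_that("tiny and non-square inputs follow the declared contracts", {
  one <- mirrorOrthotropic(labelImage(matrix(0L, 1, 1), 1))
  expect_identical(labels(one), matrix(0L, 2, 2))
  expect_true(verifyPeriodicity(one@labels)$ok)
  expect_error(mirrorOrthotropic(labelImage(matrix(0L, 2, 3), 1)),
               "square")
})

test_that("mirrored RVE fabric stays axis-aligned", {
  g <- generateMicrostructure(alignmentSpec(5))
  fr <- fabricAnalysis(g$label, phase = "lumen", seed = 5)
  rc <- rotateAndCrop(g$label, angleDeg = as.numeric(principalAngle(fr@fit)),
                      outSizePx = 170)
  rve <- mirrorOrthotropic(rc$label)
  dev <- verifyPrincipalAlignment(rve@labels, phase = "lumen", seed = 51)
  expect_lte(as.numeric(dev), 2)
})

test_that("a random raster is reported aperiodic", {
  set.seed(12)
  lab <- labelImage(matrix(sample(0:2, 400, replace = TRUE), 20, 20), 1)
  rep <- verifyPeriodicity(lab)
  expect_false(rep$ok)
  expect_gt(nrow(rep$mismatches), 0)
  ## single-phase raster is trivially periodic
  expect_true(verifyPeriodicity(labelImage(matrix(1L, 5, 5), 1))$ok)
})
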