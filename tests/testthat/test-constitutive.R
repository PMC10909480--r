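test_that("the reference state has zero energy and stress for any material", {
  Fi <- diag(2)
  for (mat in list(neoHookean(7), neoHookean(0.5, nu = 0.45),
                   hgo(17.5, 155, 200, 0), hgo(5, 300, 50, 1 / 3),
                   hgo(30, 10, 200, 0.2))) {
    st <- deformationState(Fi, 1, 0)
    expect_equal(strainEnergy(st, mat), 0)
    expect_equal(max(abs(cauchyStress(st, mat))), 0)
  }
})

test_that("closed forms: isochoric uniaxial and pure dilation", {
  C10 <- 8; D1 <- 0.02
  m <- neoHookean(C10, D1 = D1)
  lam <- 1.07
  st <- deformationState(diag(c(lam, 1 / sqrt(lam))), 1 / sqrt(lam))
  expect_equal(strainEnergy(st, m), C10 * (lam^2 + 2 / lam - 3),
               tolerance = 1e-12)
  ## pure dilation J = 1.1 with no distortion: only the volumetric term
  s <- 1.1^(1 / 3)
  std <- deformationState(diag(c(s, s)), s)
  expect_equal(strainEnergy(std, m), (1 / D1) * 0.1^2, tolerance = 1e-12)
})

test_that("kappa = 0 fibres deactivate bit-wise under fibre compression", {
  mh <- hgo(17.5, 155, 200, 0)
  mn <- neoHookean(17.5)
  ## compression along the fibre (x), isochoric-ish
  st <- deformationState(matrix(c(0.95, 0, 0, 1.02), 2, 2), 1.03, 0)
  expect_identical(strainEnergy(st, mh), strainEnergy(st, mn))
  expect_identical(cauchyStress(st, mh), cauchyStress(st, mn))
  expect_identical(materialTangent(st, mh), materialTangent(st, mn))
})

test_that("the aligned fibre term matches its scalar closed form", {
  C10 <- 5; k1 <- 100; k2 <- 150
  mh <- hgo(C10, k1, k2, 0)
  mn <- neoHookean(C10)
  lam <- 1.05
  st <- deformationState(diag(c(lam, 1 / sqrt(lam))), 1 / sqrt(lam), 0)
  I4b <- lam^2                       # J = 1 so no volumetric scaling
  fib <- k1 / (2 * k2) * (exp(k2 * (I4b - 1)^2) - 1)
  expect_equal(strainEnergy(st, mh) - strainEnergy(st, mn), fib,
               tolerance = 1e-10)
})

test_that("analytic stress and tangent agree with central differences", {
  mats <- list(neoHookean(12, nu = 0.48), hgo(17.5, 155, 200, 0),
               hgo(8, 40, 20, 0.25))
  sts <- randomStates(12, seed = 5)
  h <- 1e-6
  for (mat in mats) {
    for (s in sts) {
      x0 <- c(as.vector(s$F), s$lambda3)
      en <- function(x) strainEnergy(
        deformationState(matrix(x[1:4], 2, 2), x[5], s$angle), mat)
      gr <- function(x) pkStress(
        deformationState(matrix(x[1:4], 2, 2), x[5], s$angle), mat)
      g <- gr(x0)
      fd <- vapply(1:5, function(i) {
        xp <- x0; xm <- x0
        xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
        (en(xp) - en(xm)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(g - fd)) / max(abs(g)), 1e-5)
      H <- materialTangent(deformationState(s$F, s$lambda3, s$angle), mat)
      fdH <- sapply(1:5, function(i) {
        xp <- x0; xm <- x0
        xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
        (gr(xp) - gr(xm)) / (2 * h)
      })
      expect_lt(max(abs(H - fdH)) / max(abs(H)), 1e-4)
    }
  }
})

test_that("the small-strain tangent at the reference is isotropic with
           shear modulus 2*C10 and positive definite", {
  C10 <- 9
  m <- neoHookean(C10, nu = 0.49)
  H <- materialTangent(deformationState(diag(2), 1), m)
  ## in-plane simple-shear stiffness d2Psi/dF12dF12 = mu = 2*C10
  expect_equal(H[3, 3], 2 * C10, tolerance = 1e-10)
  expect_equal(H[2, 2], 2 * C10, tolerance = 1e-10)
  ## convexity on symmetric in-plane strains after lambda3 condensation
  A <- planeStressCondense(diag(2), m)$tangent
  B <- cbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 1, 1, 0) / sqrt(2))
  Ks <- t(B) %*% A %*% B
  expect_true(all(eigen(Ks, symmetric = TRUE)$values > 0))
})

test_that("energy is frame indifferent under in-plane rotations", {
  m <- hgo(10, 80, 100, 0.1)
  sts <- randomStates(6, seed = 8)
  for (s in sts) {
    e0 <- strainEnergy(deformationState(s$F, s$lambda3, s$angle), m)
    for (beta in c(15, 67, -40)) {
      R <- matrix(c(cospi(beta / 180), sinpi(beta / 180),
                    -sinpi(beta / 180), cospi(beta / 180)), 2, 2)
      ## rotating the observer: F -> R F, fibre direction unchanged in the
      ## reference configuration
      e1 <- strainEnergy(deformationState(R %*% s$F, s$lambda3, s$angle), m)
      expect_lt(abs(e1 - e0), 1e-10 * max(1, abs(e0)))
    }
  }
})

test_that("kappa = 1/3 energy is independent of the fibre angle", {
  m <- hgo(10, 80, 100, 1 / 3)
  for (s in randomStates(5, seed = 9)) {
    es <- vapply(c(-60, 0, 30, 85), function(a)
      strainEnergy(deformationState(s$F, s$lambda3, a), m), numeric(1))
    expect_lt(max(es) - min(es), 1e-12 * max(1, abs(es[1])))
  }
})

test_that("plane-stress condensation drives sigma33 to zero", {
  expect_equal(planeStressCondense(diag(2), neoHookean(5))$lambda3, 1,
               tolerance = 1e-9)
  ## near-incompressible equibiaxial: lambda3 -> 1/lambda^2
  m <- neoHookean(5, nu = 0.4999)
  lam <- 1.04
  ps <- planeStressCondense(diag(c(lam, lam)), m)
  expect_equal(ps$lambda3, 1 / lam^2, tolerance = 1e-3)
  for (s in randomStates(10, seed = 10)) {
    ps <- planeStressCondense(s$F, hgo(17.5, 155, 200, 0),
                              fiberAngleDeg = s$angle)
    scl <- max(1, sqrt(sum(ps$sigma^2)))
    expect_lt(abs(ps$sigma[3, 3]), 1e-10 * scl)
  }
})

test_that("incompressible-limit uniaxial stress approaches 2*C10*(l^2 - 1/l)", {
  C10 <- 6
  m <- neoHookean(C10, nu = 0.49995)
  lam <- 1.05
  s <- pointMacroResponse(m, "uniaxial-1", 1, lam - 1)
  expect_equal(s$sigma[1, 1], 2 * C10 * (lam^2 - 1 / lam),
               tolerance = 2e-3)
})

test_that("invalid parameters and states are rejected", {
  expect_error(hgo(10, 50, 100, kappa = 0.5), "kappa")
  expect_error(neoHookean(-1), "C10")
  expect_error(validObject(deformationState(diag(c(1, -1)), 1)), "det")
  expect_error(planeStressCondense(diag(c(1, -1)), neoHookean(1)), "det")
  ## HGO without a fibre angle is an error
  expect_error(strainEnergy(deformationState(diag(2), 1), hgo(1, 1, 1)),
               "fiber angle")
})
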