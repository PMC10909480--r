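# shared fixtures: all built in code at test time

# parallel stripes of stroma (label 0) on epithelium (label 1) at a given
# axial angle; W x W raster, stripe half-period `half` pixels
stripeLabel <- function(angleDeg, W = 128, half = 8, pixelSizeUm = 1) {
  x <- outer(rep(1, W), seq_len(W) - 0.5)
  y <- outer(seq_len(W) - 0.5, rep(1, W))
  d <- -sinpi(angleDeg / 180) * x + cospi(angleDeg / 180) * y
  labelImage(matrix(as.integer((d %% (2 * half)) >= half), W, W),
             pixelSizeUm)
}

# centred disk mask
diskMask <- function(W = 101, R = 30) {
  x <- outer(rep(1, W), seq_len(W) - 0.5) - W / 2
  y <- outer(seq_len(W) - 0.5, rep(1, W)) - W / 2
  x^2 + y^2 <= R^2
}

# antipodal point cloud sampled on a parametric origin-centred ellipse
ellipseCloud <- function(a, b, angleDeg, n = 360) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- angleDeg * pi / 180
  x <- b * cos(t) * cos(phi) - a * sin(t) * sin(phi)
  y <- b * cos(t) * sin(phi) + a * sin(t) * cos(phi)
  new("MILPointCloud", points = cbind(x, y), directionsUsed = as.integer(n),
      lineSpacingPx = 1, seed = 1L, degenerate = FALSE)
}

# absolute axial angle difference in degrees (theta == theta + 180)
axialDiff <- function(a, b) {
  d <- abs(((a - b + 90) %% 180) - 90)
  pmin(d, 180 - d)
}

# random admissible deformation states near the reference
randomStates <- function(n, seed = 42, spread = 0.06) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(2) + matrix(stats::runif(4, -spread, spread), 2, 2)
      if (det(F) > 0.5) break
    }
    list(F = F, lambda3 = exp(stats::runif(1, -spread, spread)),
         angle = stats::runif(1, -90, 90))
  })
}

# single-point macroscopic response under the same boundary conditions as
# the homogenization tests (uniaxial macro stress / symmetric shear),
# solved on the condensed plane-stress point: the homogeneous-RVE oracle
pointMacroResponse <- function(material, kind, sign, magnitude = 0.05,
                               fiberAngleDeg = NA) {
  g <- sign * magnitude
  Fof <- function(x) {
    switch(kind,
      "uniaxial-1" = matrix(c(1 + g, 0, 0, 1 + x[1]), 2, 2),
      "uniaxial-2" = matrix(c(1 + x[1], 0, 0, 1 + g), 2, 2),
      "shear-12"   = matrix(c(1 + x[1], g / 2, g / 2, 1 + x[2]), 2, 2))
  }
  nfree <- if (kind == "shear-12") 2L else 1L
  resid <- function(x) {
    P <- planeStressCondense(Fof(x), material, fiberAngleDeg)$P
    if (kind == "uniaxial-1") P[4] else if (kind == "uniaxial-2") P[1]
    else c(P[1], P[4])
  }
  x <- rep(0, nfree)
  for (it in 1:60) {
    r <- resid(x)
    if (max(abs(r)) < 1e-12 * max(1, abs(g) * 100)) break
    h <- 1e-7
    J <- sapply(seq_len(nfree), function(k) {
      xp <- x; xp[k] <- xp[k] + h
      (resid(xp) - r) / h
    })
    x <- x - solve(matrix(J, nfree, nfree), r)
  }
  ps <- planeStressCondense(Fof(x), material, fiberAngleDeg)
  list(F = Fof(x), sigma = ps$sigma, lambda3 = ps$lambda3)
}

# secant modulus of the single-point response for one of the six cases
pointModulus <- function(material, kind, sign, magnitude = 0.05,
                         fiberAngleDeg = NA) {
  s <- pointMacroResponse(material, kind, sign, magnitude, fiberAngleDeg)
  comp <- switch(kind, "uniaxial-1" = s$sigma[1, 1],
                 "uniaxial-2" = s$sigma[2, 2], "shear-12" = s$sigma[1, 2])
  abs(comp) / magnitude
}

# small periodic all-stroma RVE (homogeneous material tests)
homogeneousModel <- function(n = 8, angleDeg = 0, pixelSizeUm = 10) {
  meshFromLabels(labelImage(matrix(0L, n, n), pixelSizeUm),
                 constantAngleDeg = angleDeg)
}

# small mirrored two-acinus RVE for parameter-sweep tests (32x32 px cell)
sweepRVE <- function(seed = 31) {
  g <- generateMicrostructure(microstructureSpec(widthPx = 16,
                                                 heightPx = 16,
                                                 pixelSizeUm = 32,
                                                 nAcini = 2,
                                                 lumenRadiusMeanUm = 50,
                                                 lumenRadiusSdUm = 8,
                                                 epitheliumThicknessUm = 35,
                                                 elongation = 1,
                                                 seed = seed))
  mirrorOrthotropic(g$label, generateFiberField(g$label, "constant", 0))
}

# the synthetic anisotropic ROI family used for alignment checks
alignmentSpec <- function(seed, preferredAngleDeg = 25) {
  microstructureSpec(nAcini = 12, lumenRadiusMeanUm = 24,
                     lumenRadiusSdUm = 5, epitheliumThicknessUm = 30,
                     elongation = 3, preferredAngleDeg = preferredAngleDeg,
                     angleDispersionDeg = 0, seed = seed)
}
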