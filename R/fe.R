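#' @include AllClasses.R constitutive.R orientation.R rve.R
NULL

blockSum <- function(m, c) {
  ## sum over c x c pixel blocks
  H <- nrow(m); W <- ncol(m)
  m2 <- matrix(colSums(matrix(m, nrow = c)), H / c, W)      # rows
  t(matrix(colSums(matrix(t(m2), nrow = c)), W / c, H / c)) # cols
}

#' Build a structured FE mesh from a periodic label raster
#'
#' One bilinear quadrilateral per \code{coarsen} x \code{coarsen} pixel
#' block. The block label is decided by majority vote with ties broken in
#' the order stroma > epithelium > lumen; stromal elements take the fibre
#' angle of the orientation map at the block centre (falling back to the
#' axial mean of the block's stromal angles when the centre pixel carries no
#' angle).
#'
#' @param rve a \linkS4class{PeriodicRVE} or \linkS4class{LabelImage}
#' @param coarsen block size in pixels; must divide both raster dimensions
#' @param orientation optional \linkS4class{OrientationMap} when \code{rve}
#'   is a LabelImage
#' @param constantAngleDeg fibre angle applied to all stromal elements when
#'   no orientation map is available
#' @return an \linkS4class{FEModel}
#' @export
meshFromLabels <- function(rve, coarsen = 1L, orientation = NULL,
                           constantAngleDeg = 0) {
  if (is(rve, "PeriodicRVE")) {
    label <- rve@labels
    if (is.null(orientation) && !is.null(rve@orientation))
      orientation <- rve@orientation
  } else label <- rve
  stopifnot(is(label, "LabelImage"))
  lab <- label@labels
  H <- nrow(lab); W <- ncol(lab)
  coarsen <- as.integer(coarsen)
  if (H %% coarsen != 0 || W %% coarsen != 0)
    stop("coarsen = ", coarsen, " does not divide the raster size ",
         W, " x ", H)
  nx <- W %/% coarsen; ny <- H %/% coarsen
  c0 <- blockSum((lab == 0L) * 1L, coarsen)
  c1 <- blockSum((lab == 1L) * 1L, coarsen)
  c2 <- blockSum((lab == 2L) * 1L, coarsen)
  ## ties.method = "first" implements the stroma > epithelium > lumen rule
  labBlock <- matrix(max.col(cbind(as.vector(c0), as.vector(c1),
                                   as.vector(c2)), ties.method = "first"),
                     ny, nx) - 1L
  px <- label@pixelSizeUm
  h <- coarsen * px
  elemLabel <- as.vector(t(labBlock))     # el = ey*nx + ex + 1
  elemAngle <- rep(NA_real_, nx * ny)
  st <- elemLabel == 0L
  if (any(st)) {
    if (!is.null(orientation)) {
      exv <- (seq_len(nx) - 0.5) * h
      eyv <- (seq_len(ny) - 0.5) * h
      cx <- rep(exv, times = ny)          # element order: ex fastest
      cy <- rep(eyv, each = nx)
      a <- windowAngleAt(orientation, cx, cy)
      need <- st & !is.finite(a)
      if (any(need)) {
        ## axial mean of the block's stromal angles (angle doubling)
        A <- orientation@angleDeg
        for (el in which(need)) {
          ex <- (el - 1L) %% nx; ey <- (el - 1L) %/% nx
          ir <- (ey * coarsen + 1L):((ey + 1L) * coarsen)
          jr <- (ex * coarsen + 1L):((ex + 1L) * coarsen)
          v <- A[ir, jr]
          v <- v[is.finite(v)]
          a[el] <- if (length(v))
            foldAngle(atan2(mean(sinpi(v / 90)), mean(cospi(v / 90))) *
                        90 / pi)
          else 0
        }
      }
      elemAngle[st] <- a[st]
    } else elemAngle[st] <- foldAngle(constantAngleDeg)
  }
  new("FEModel", nx = as.integer(nx), ny = as.integer(ny), hUm = h,
      elemLabel = as.integer(elemLabel), elemAngleDeg = elemAngle)
}

#' Periodic node pairings for a structured mesh
#'
#' Pairs each right-edge node with its left-edge partner and each top-edge
#' node with its bottom partner; the three non-origin corners are identified
#' with the origin corner. Every boundary node appears in exactly one
#' pairing, and the origin node is pinned to zero displacement to remove
#' rigid translation. Slave displacements obey
#' u(x+) - u(x-) = H (x+ - x-) with H the macroscopic displacement-gradient
#' reference DOFs.
#'
#' @param model an \linkS4class{FEModel}
#' @return a \linkS4class{PBCConstraints}
#' @export
periodicCouplings <- function(model) {
  stopifnot(is(model, "FEModel"))
  nx <- model@nx; ny <- model@ny; h <- model@hUm
  nid <- function(ix, iy) iy * (nx + 1L) + ix + 1L
  Lx <- nx * h; Ly <- ny * h
  iy <- seq_len(ny - 1L)
  ix <- seq_len(nx - 1L)
  pairs <- rbind(
    data.frame(slave = nid(nx, iy), master = nid(0L, iy), dx = Lx, dy = 0),
    data.frame(slave = nid(ix, ny), master = nid(ix, 0L), dx = 0, dy = Ly),
    data.frame(slave = nid(nx, 0L), master = nid(0L, 0L), dx = Lx, dy = 0),
    data.frame(slave = nid(0L, ny), master = nid(0L, 0L), dx = 0, dy = Ly),
    data.frame(slave = nid(nx, ny), master = nid(0L, 0L), dx = Lx, dy = Ly))
  if (anyDuplicated(pairs$slave))
    stop("redundant constraint: a boundary node is paired twice")
  new("PBCConstraints", pairs = pairs, pinned = nid(0L, 0L),
      nNodes = (nx + 1L) * (ny + 1L))
}

# Build the sparse transformation u_full = T %*% c(utilde, H) with the
# affine/fluctuation split u = H X + utilde: the H columns carry the affine
# field at every node, the fluctuation columns are shared between periodic
# partners (and zero at the pinned node). This keeps
# u(x+) - u(x-) = H (x+ - x-) exactly and gives Newton an affine initial
# state at every load increment.
feContext <- function(model, constraints = periodicCouplings(model)) {
  nx <- model@nx; ny <- model@ny; h <- model@hUm
  nnode <- constraints@nNodes
  ndof <- 2L * nnode
  slave <- constraints@pairs$slave
  master <- constraints@pairs$master
  pin <- constraints@pinned
  isSlave <- rep(FALSE, nnode); isSlave[slave] <- TRUE
  red <- setdiff(which(!isSlave), pin)    # nodes with their own dofs
  colOf <- integer(nnode)
  colOf[red] <- seq_along(red)
  nRed <- length(red)
  cH <- 2L * nRed + 1:4                   # columns H11, H22, H12, H21
  ti <- c(rbind(2L * red - 1L, 2L * red))
  tj <- seq_len(2L * nRed)
  tv <- rep(1, 2L * nRed)
  mRed <- colOf[master]                   # 0 when master is pinned
  keep <- mRed > 0L
  ti <- c(ti, 2L * slave[keep] - 1L, 2L * slave[keep])
  tj <- c(tj, 2L * mRed[keep] - 1L, 2L * mRed[keep])
  tv <- c(tv, rep(1, 2L * sum(keep)))
  ## affine columns: every node at reference coordinates (X, Y)
  allN <- seq_len(nnode)
  X <- ((allN - 1L) %% (nx + 1L)) * h
  Y <- ((allN - 1L) %/% (nx + 1L)) * h
  ti <- c(ti, 2L * allN - 1L, 2L * allN - 1L, 2L * allN, 2L * allN)
  tj <- c(tj, rep(cH[1], nnode), rep(cH[3], nnode),
          rep(cH[4], nnode), rep(cH[2], nnode))
  tv <- c(tv, X, Y, X, Y)
  Tmat <- Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                               dims = c(ndof, 2L * nRed + 4L))
  ## sparsity pattern of the element-assembled stiffness
  ex <- (seq_len(nx * ny) - 1L) %% nx
  ey <- (seq_len(nx * ny) - 1L) %/% nx
  n1 <- ey * (nx + 1L) + ex + 1L
  edof <- cbind(2L * n1 - 1L, 2L * n1,
                2L * (n1 + 1L) - 1L, 2L * (n1 + 1L),
                2L * (n1 + nx + 2L) - 1L, 2L * (n1 + nx + 2L),
                2L * (n1 + nx + 1L) - 1L, 2L * (n1 + nx + 1L))
  Ki <- as.vector(t(edof[, rep(1:8, each = 8)]))  # row index varies fastest
  Kj <- as.vector(t(edof[, rep(1:8, times = 8)]))
  list(model = model, constraints = constraints, Tmat = Tmat,
       nRed = nRed, cH = cH, ndof = ndof, Ki = Ki, Kj = Kj,
       V0 = (nx * h) * (ny * h))
}

matTable <- function(materials) {
  if (is(materials, "NeoHookean"))
    materials <- list(stroma = materials, epithelium = materials,
                      lumen = materials)
  stopifnot(is.list(materials))
  need <- c("stroma", "epithelium", "lumen")
  if (!all(need %in% names(materials)))
    stop("materials must name stroma, epithelium and lumen")
  rbind(matVector(materials$stroma), matVector(materials$epithelium),
        matVector(materials$lumen))
}

#' Benchmark material set
#'
#' The stromal HGO point chosen by benchmarking against the literature
#' compressive range (C10 = 17.5 kPa, k1 = 155 kPa, k2 = 200, kappa = 0)
#' plus geometric mid-range neo-Hookean parameters for the epithelial
#' compartment (C10 range 0.192-4.801 kPa) and the acinar lumen (C10 range
#' 1.92-192 kPa).
#'
#' @param nu effective Poisson ratio for all constituents
#' @return named list of materials
#' @export
defaultMaterials <- function(nu = 0.49) {
  list(stroma = hgo(17.5, 155, 200, 0, nu = nu),
       epithelium = neoHookean(sqrt(0.192 * 4.801), nu = nu),
       lumen = neoHookean(sqrt(1.92 * 192), nu = nu))
}

caseTargets <- function(case, transverse) {
  g <- case@sign * case@magnitude
  ## H ordering: (H11, H22, H12, H21); NA = free
  switch(case@kind,
    "uniaxial-1" = c(g, if (transverse == "free") NA else 0, 0, 0),
    "uniaxial-2" = c(if (transverse == "free") NA else 0, g, 0, 0),
    "shear-12"   = c(if (transverse == "free") NA else 0,
                     if (transverse == "free") NA else 0, g / 2, g / 2))
}

#' Solve one macroscopic load case on a periodic RVE
#'
#' Incremental Newton-Raphson on the total Lagrangian plane-stress
#' equilibrium with periodic boundary conditions. Uniaxial cases prescribe
#' the normal component of the macroscopic displacement gradient (and zero
#' macro shear) and leave the transverse normal component free with zero
#' conjugate macro force (uniaxial macro stress, the default); the shear
#' case prescribes the symmetric pair H12 = H21 = gamma/2. On Newton
#' divergence the increment is halved automatically (3 levels) before
#' giving up.
#'
#' @param model an \linkS4class{FEModel}
#' @param materials named list (stroma, epithelium, lumen) of material
#'   objects, or one material for all phases
#' @param case a \linkS4class{MacroLoadCase}
#' @param nIncrements load increments (default 5)
#' @param maxIter Newton iterations per increment
#' @param tolRel relative residual tolerance
#' @param transverse "free" (uniaxial macro stress) or "fixed" (fully
#'   prescribed macro strain)
#' @param ctx optional precomputed context (internal reuse)
#' @return list: volume-averaged Cauchy stress \code{sigmaAvg} (s11, s22,
#'   s12, in kPa, averaged over the deformed volume), macro first
#'   Piola-Kirchhoff stress \code{Pbar} from the reference-DOF reactions,
#'   \code{Fbar}, \code{hillMandel} relative consistency error,
#'   \code{energy}, \code{converged}, \code{residuals}
#' @export
solveLoadCase <- function(model, materials, case, nIncrements = 5L,
                          maxIter = 25L, tolRel = 1e-10,
                          transverse = c("free", "fixed"), ctx = NULL) {
  stopifnot(is(model, "FEModel"), is(case, "MacroLoadCase"))
  transverse <- match.arg(transverse)
  if (is.null(ctx)) ctx <- feContext(model)
  mats <- matTable(materials)
  nx <- model@nx; ny <- model@ny; h <- model@hUm
  eangle <- model@elemAngleDeg * pi / 180
  eangle[!is.finite(eangle)] <- 0
  target <- caseTargets(case, transverse)
  presc <- which(!is.na(target))
  free <- which(is.na(target))
  Tf <- ctx$Tmat[, c(seq_len(2L * ctx$nRed), ctx$cH[free]), drop = FALSE]
  Tp <- ctx$Tmat[, ctx$cH[presc], drop = FALSE]
  TH <- ctx$Tmat[, ctx$cH, drop = FALSE]

  nfree <- ncol(Tf)
  q <- numeric(nfree)
  l3 <- rep(1, 4L * nx * ny)
  resHist <- numeric(0)
  tDone <- 0; dt <- 1 / nIncrements
  nHalve <- 0
  uFull <- NULL; out <- NULL
  while (tDone < 1 - 1e-12) {
    step <- min(dt, 1 - tDone)
    tTry <- tDone + step
    hp <- target[presc] * tTry
    qTry <- q; l3Try <- l3
    okInc <- FALSE
    for (it in seq_len(maxIter)) {
      uFull <- as.numeric(Tf %*% qTry + (if (length(presc)) Tp %*% hp else 0))
      out <- .cpp_assemble(uFull, nx, ny, h, model@elemLabel, eangle,
                           mats, l3Try, TRUE)
      if (!out$ok) break
      l3Try <- out$l3cache
      Rf <- as.numeric(Matrix::crossprod(Tf, out$resid))
      rn <- sqrt(sum(Rf^2))
      refN <- max(1e-8, sqrt(sum(as.numeric(
        Matrix::crossprod(TH, out$resid))^2)))
      resHist <- c(resHist, rn)
      if (rn <= tolRel * refN) { okInc <- TRUE; break }
      K <- Matrix::sparseMatrix(i = ctx$Ki, j = ctx$Kj, x = out$Kvals,
                                dims = c(ctx$ndof, ctx$ndof))
      Kf <- Matrix::forceSymmetric(Matrix::crossprod(Tf, K %*% Tf))
      dq <- tryCatch(as.numeric(Matrix::solve(Kf, Rf)),
                     error = function(e) NULL)
      if (is.null(dq) || !all(is.finite(dq))) break
      qTry <- qTry - dq
    }
    if (okInc) {
      q <- qTry; l3 <- l3Try; tDone <- tTry
    } else {
      nHalve <- nHalve + 1
      dt <- dt / 2
      if (nHalve > 3)
        stop("Newton divergence after 3 increment halvings; residual ",
             "history: ", paste(signif(utils::tail(resHist, 8), 3),
                                collapse = ", "))
    }
  }
  ## averages and macro reactions at the converged state
  sigmaAvg <- c(out$sumPF[1], out$sumPF[4],
                0.5 * (out$sumPF[2] + out$sumPF[3])) / out$sumJ
  RH <- as.numeric(Matrix::crossprod(TH, out$resid))
  Pbar <- matrix(c(RH[1], RH[4], RH[3], RH[2]), 2, 2) / ctx$V0
  Hfin <- target
  Hfin[presc] <- target[presc]
  if (length(free)) Hfin[free] <- q[2L * ctx$nRed + seq_along(free)]
  Fbar <- matrix(c(1 + Hfin[1], Hfin[4], Hfin[3], 1 + Hfin[2]), 2, 2)
  sigMacro <- (Pbar %*% t(Fbar)) * ctx$V0 / out$sumJ
  sigMacroV <- c(sigMacro[1, 1], sigMacro[2, 2],
                 0.5 * (sigMacro[1, 2] + sigMacro[2, 1]))
  hm <- max(abs(sigmaAvg - sigMacroV)) / max(max(abs(sigmaAvg)), 1e-12)
  list(case = case, sigmaAvg = sigmaAvg, Pbar = Pbar, Fbar = Fbar,
       Hbar = Hfin, hillMandel = hm, energy = out$energy,
       meanJ = out$sumJ / ctx$V0, converged = TRUE, residuals = resHist,
       u = uFull)
}

#' Solve the six standard load cases (+/- uniaxial-1, uniaxial-2, shear-12)
#'
#' @inheritParams solveLoadCase
#' @param magnitude global test strain (default 0.05)
#' @return named list of case results: \code{uni1+}, \code{uni1-},
#'   \code{uni2+}, \code{uni2-}, \code{shear+}, \code{shear-}
#' @export
solveAllCases <- function(model, materials, magnitude = 0.05, ...) {
  ctx <- feContext(model)
  run <- function(kind, s) solveLoadCase(model, materials,
                                         macroLoadCase(kind, s, magnitude),
                                         ctx = ctx, ...)
  list("uni1+" = run("uniaxial-1", 1), "uni1-" = run("uniaxial-1", -1),
       "uni2+" = run("uniaxial-2", 1), "uni2-" = run("uniaxial-2", -1),
       "shear+" = run("shear-12", 1), "shear-" = run("shear-12", -1))
}

#' Apparent secant moduli from the six load cases
#'
#' E11 = <sigma11>/eps for the tension case and |<sigma11>|/eps under
#' compression (analogously E22); G12 = <sigma12>/gamma with gamma the
#' engineering shear strain. All in kPa.
#'
#' @param results the list returned by \code{\link{solveAllCases}}
#' @return an \linkS4class{ApparentModuli}
#' @export
apparentModuli <- function(results) {
  need <- c("uni1+", "uni1-", "uni2+", "uni2-", "shear+", "shear-")
  if (!all(need %in% names(results)))
    stop("missing case(s): ", paste(setdiff(need, names(results)),
                                    collapse = ", "))
  eps <- vapply(results, function(r) r$case@magnitude, numeric(1))
  new("ApparentModuli",
      E11t = results[["uni1+"]]$sigmaAvg[1] / eps[["uni1+"]],
      E11c = abs(results[["uni1-"]]$sigmaAvg[1]) / eps[["uni1-"]],
      E22t = results[["uni2+"]]$sigmaAvg[2] / eps[["uni2+"]],
      E22c = abs(results[["uni2-"]]$sigmaAvg[2]) / eps[["uni2-"]],
      G12t = results[["shear+"]]$sigmaAvg[3] / eps[["shear+"]],
      G12c = abs(results[["shear-"]]$sigmaAvg[3]) / eps[["shear-"]])
}

#' Homogenize a periodic RVE in one call
#'
#' Meshes the RVE, solves all six load cases and returns the apparent
#' moduli.
#'
#' @param rve a \linkS4class{PeriodicRVE}
#' @param materials material set (see \code{\link{solveLoadCase}})
#' @param coarsen mesh coarsening factor
#' @param ... passed to \code{\link{solveAllCases}}
#' @return list with \code{moduli}, \code{cases}, \code{fractions}
#' @export
homogenizeRVE <- function(rve, materials = defaultMaterials(), coarsen = 1L,
                          ...) {
  model <- meshFromLabels(rve, coarsen = coarsen)
  cases <- solveAllCases(model, materials, ...)
  list(moduli = apparentModuli(cases), cases = cases,
       fractions = areaFractions(rve@labels))
}

#' RVE-size convergence study
#'
#' Crops centred square windows of increasing physical size from a source
#' image, mirrors each into a periodic RVE, homogenizes it, and tabulates
#' the six apparent moduli and the area fractions. The convergence size is
#' the smallest size beyond which every tracked quantity changes by less
#' than \code{tolFrac} between consecutive sizes.
#'
#' @param label a source \linkS4class{LabelImage}
#' @param sizesUm increasing pre-mirror window sizes (um)
#' @param materials material set
#' @param orientation optional \linkS4class{OrientationMap}
#' @param coarsen mesh coarsening per size (scalar or vector)
#' @param tolFrac convergence threshold on relative change (default 0.02)
#' @param ... passed to \code{\link{solveAllCases}}
#' @return data.frame (one row per size) with attribute
#'   \code{convergedSizeUm} (NA when not reached)
#' @export
rveConvergenceStudy <- function(label, sizesUm, materials =
                                  defaultMaterials(), orientation = NULL,
                                coarsen = 1L, tolFrac = 0.02, ...) {
  stopifnot(is(label, "LabelImage"), !is.unsorted(sizesUm))
  px <- label@pixelSizeUm
  coarsen <- rep_len(coarsen, length(sizesUm))
  rows <- vector("list", length(sizesUm))
  for (k in seq_along(sizesUm)) {
    rows[[k]] <- tryCatch({
      sPx <- round(sizesUm[k] / px)
      sPx <- sPx - (sPx %% coarsen[k])
      rc <- rotateAndCrop(label, orientation, angleDeg = 0,
                          outSizePx = sPx)
      rve <- mirrorOrthotropic(rc$label, rc$orientation)
      res <- homogenizeRVE(rve, materials, coarsen = coarsen[k], ...)
      m <- res$moduli
      fr <- res$fractions
      data.frame(sizeUm = sizesUm[k], E11t = m@E11t, E11c = m@E11c,
                 E22t = m@E22t, E22c = m@E22c, G12t = m@G12t,
                 G12c = m@G12c, fS = fr[1], fE = fr[2], fA = fr[3],
                 failed = FALSE)
    }, error = function(e)
      data.frame(sizeUm = sizesUm[k], E11t = NA, E11c = NA, E22t = NA,
                 E22c = NA, G12t = NA, G12c = NA, fS = NA, fE = NA,
                 fA = NA, failed = TRUE))
  }
  tab <- do.call(rbind, rows)
  conv <- NA_real_
  if (nrow(tab) >= 2) {
    qcols <- c("E11t", "E11c", "E22t", "E22c", "G12t", "G12c",
               "fS", "fE", "fA")
    ok <- !tab$failed
    rel <- sapply(qcols, function(cn) {
      v <- tab[[cn]]
      c(NA, abs(diff(v)) / pmax(abs(v[-length(v)]), 1e-12))
    })
    good <- apply(rel < tolFrac, 1, all)
    good[1] <- FALSE
    ## smallest size from which all later consecutive changes stay small
    for (k in seq_len(nrow(tab))[-1]) {
      if (all(good[k:nrow(tab)]) && all(ok)) { conv <- tab$sizeUm[k - 1]; break }
    }
  }
  attr(tab, "convergedSizeUm") <- conv
  rownames(tab) <- NULL
  tab
}
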