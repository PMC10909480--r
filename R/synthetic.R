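#' @include AllClasses.R utils.R
NULL

#' Specify a synthetic three-phase microstructure
#'
#' Parameters of the seeded generator emulating normal glandular histology:
#' elliptical acini (a lumen core ringed by an epithelial compartment of
#' fixed thickness) embedded by dart throwing in a connected stromal matrix.
#' Defaults describe a quadrant of roughly one converged RVE of normal
#' prostate tissue: ~1 mm of tissue with acini of a few hundred micrometres
#' outer diameter.
#'
#' @param widthPx,heightPx raster size (pixels)
#' @param pixelSizeUm micrometres per pixel
#' @param nAcini number of acini to place
#' @param lumenRadiusMeanUm,lumenRadiusSdUm mean and s.d. of the lumen
#'   semi-minor radius (um)
#' @param epitheliumThicknessUm thickness of the epithelial ring (um)
#' @param elongation acinus major/minor axis ratio (>= 1)
#' @param preferredAngleDeg mean acinus orientation, degrees in [-90, 90)
#' @param angleDispersionDeg s.d. of acinus orientations about the mean
#' @param seed integer seed (same spec + seed => bit-identical output)
#' @return a \linkS4class{MicrostructureSpec}
#' @export
microstructureSpec <- function(widthPx = 256L, heightPx = 256L,
                               pixelSizeUm = 4,
                               nAcini = 16L,
                               lumenRadiusMeanUm = 40,
                               lumenRadiusSdUm = 8,
                               epitheliumThicknessUm = 46,
                               elongation = 1.6,
                               preferredAngleDeg = 0,
                               angleDispersionDeg = 10,
                               seed = 1L) {
  new("MicrostructureSpec",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      pixelSizeUm = pixelSizeUm, nAcini = as.integer(nAcini),
      lumenRadiusMeanUm = lumenRadiusMeanUm,
      lumenRadiusSdUm = lumenRadiusSdUm,
      epitheliumThicknessUm = epitheliumThicknessUm,
      elongation = elongation,
      preferredAngleDeg = foldAngle(preferredAngleDeg),
      angleDispersionDeg = angleDispersionDeg, seed = as.integer(seed))
}

#' Generate a synthetic three-phase microstructure
#'
#' Places non-overlapping elliptical acini on a stromal background by dart
#' throwing (at most 1e4 attempts per acinus; a packing that cannot be
#' completed raises an error rather than returning partial output). Each
#' acinus is a lumen ellipse surrounded by an epithelial ring of the
#' requested thickness. Acini keep at least one pixel of stroma between
#' themselves and the image border, so the stromal phase is a single
#' 4-connected component by construction.
#'
#' @param spec a \linkS4class{MicrostructureSpec}
#' @return list with elements \code{label} (a \linkS4class{LabelImage}) and
#'   \code{truth} (a \linkS4class{GroundTruth} whose area fractions match the
#'   raster exactly)
#' @export
generateMicrostructure <- function(spec) {
  stopifnot(is(spec, "MicrostructureSpec"))
  validObject(spec)
  px <- spec@pixelSizeUm
  W <- spec@widthPx * px
  H <- spec@heightPx * px
  set.seed(spec@seed)

  n <- spec@nAcini
  centres <- matrix(numeric(0), 0, 2)
  axes <- matrix(numeric(0), 0, 2)  # lumen (minor, major)
  angs <- numeric(0)
  outerA <- numeric(0)              # outer semi-major incl. ring
  outerB <- numeric(0)              # outer semi-minor incl. ring
  margin <- 1.5 * px                # stromal gap: keeps stroma connected
  ## support function of a centred ellipse (semi-axes A >= B, major axis at
  ## theta) in direction phi; two convex acini are disjoint whenever the
  ## centre distance exceeds the sum of their support radii along the
  ## centre-to-centre direction.
  supportR <- function(A, B, thetaDeg, phi) {
    d <- phi - thetaDeg * pi / 180
    sqrt((A * cos(d))^2 + (B * sin(d))^2)
  }
  for (k in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(10000L)) {
      rMin <- stats::rnorm(1, spec@lumenRadiusMeanUm, spec@lumenRadiusSdUm)
      if (rMin < 0.25 * spec@lumenRadiusMeanUm) next
      rMaj <- rMin * spec@elongation
      th <- foldAngle(spec@preferredAngleDeg +
                        stats::rnorm(1, 0, spec@angleDispersionDeg))
      A <- rMaj + spec@epitheliumThicknessUm
      B <- rMin + spec@epitheliumThicknessUm
      if (A + margin >= W / 2 || A + margin >= H / 2) next
      cx <- stats::runif(1, A + margin, W - A - margin)
      cy <- stats::runif(1, A + margin, H - A - margin)
      okSep <- TRUE
      if (nrow(centres)) {
        dx <- cx - centres[, 1]
        dy <- cy - centres[, 2]
        d <- sqrt(dx^2 + dy^2)
        phi <- atan2(dy, dx)
        okSep <- all(d > supportR(outerA, outerB, angs, phi) +
                       supportR(A, B, th, phi) + margin)
      }
      if (okSep) {
        centres <- rbind(centres, c(cx, cy))
        axes <- rbind(axes, c(rMin, rMaj))
        angs <- c(angs, th)
        outerA <- c(outerA, A)
        outerB <- c(outerB, B)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible spec: dart throwing failed to place acinus ", k,
           " after 10000 attempts")
  }

  lab <- matrix(LABEL_STROMA, spec@heightPx, spec@widthPx)
  if (n > 0) {
    xc <- (seq_len(spec@widthPx) - 0.5) * px
    yc <- (seq_len(spec@heightPx) - 0.5) * px
    for (k in seq_len(n)) {
      rb <- outerA[k]
      jr <- which(xc >= centres[k, 1] - rb - px & xc <= centres[k, 1] + rb + px)
      ir <- which(yc >= centres[k, 2] - rb - px & yc <= centres[k, 2] + rb + px)
      dx <- outer(rep(1, length(ir)), xc[jr]) - centres[k, 1]
      dy <- outer(yc[ir], rep(1, length(jr))) - centres[k, 2]
      ct <- cospi(angs[k] / 180); st <- sinpi(angs[k] / 180)
      u <- dx * ct + dy * st     # along major axis
      v <- -dx * st + dy * ct    # along minor axis
      t0 <- spec@epitheliumThicknessUm
      inner <- (u / axes[k, 2])^2 + (v / axes[k, 1])^2 <= 1
      outer_ <- (u / (axes[k, 2] + t0))^2 + (v / (axes[k, 1] + t0))^2 <= 1
      blk <- lab[ir, jr, drop = FALSE]
      blk[outer_ & !inner] <- LABEL_EPITHELIUM
      blk[inner] <- LABEL_LUMEN
      lab[ir, jr] <- blk
    }
  }
  label <- labelImage(lab, px)
  truth <- new("GroundTruth",
               areaFractions = areaFractions(label),
               centres = centres, axes = axes, angles = angs,
               truePreferredAngleDeg = spec@preferredAngleDeg)
  list(label = label, truth = truth)
}

#' Per-phase area fractions of a label raster
#'
#' Pixel counts divided by the total pixel count; the three fractions sum to
#' one exactly in exact arithmetic.
#'
#' @param label a \linkS4class{LabelImage}
#' @return named numeric vector (stroma, epithelium, lumen)
#' @export
areaFractions <- function(label) {
  stopifnot(is(label, "LabelImage"))
  tot <- length(label@labels)
  c(stroma = sum(label@labels == 0L) / tot,
    epithelium = sum(label@labels == 1L) / tot,
    lumen = sum(label@labels == 2L) / tot)
}

#' Synthesize a stromal collagen fibre field
#'
#' \code{constant} assigns one axial angle to every stromal pixel.
#' \code{channel_tangent} orients fibres along the stromal channels: at each
#' stromal pixel the direction perpendicular to the gradient of the
#' (smoothed) distance-to-nonstroma transform, i.e. tangential to the nearest
#' acinus boundary. Non-stromal pixels carry NA.
#'
#' @param label a \linkS4class{LabelImage}
#' @param mode "constant" or "channel_tangent"
#' @param angleDeg the angle for constant mode (degrees)
#' @param sigmaPx smoothing scale of the distance field (pixels)
#' @return an \linkS4class{OrientationMap}
#' @export
generateFiberField <- function(label, mode = c("constant", "channel_tangent"),
                               angleDeg = 0, sigmaPx = 2) {
  stopifnot(is(label, "LabelImage"))
  mode <- match.arg(mode)
  stroma <- label@labels == 0L
  if (!any(stroma)) stop("no stromal pixels: fibre field undefined")
  ang <- matrix(NA_real_, nrow(label@labels), ncol(label@labels))
  coh <- matrix(NA_real_, nrow(label@labels), ncol(label@labels))
  if (mode == "constant") {
    ang[stroma] <- foldAngle(angleDeg)
    coh[stroma] <- 1
  } else {
    if (all(stroma)) {
      ang[stroma] <- 0  # no channels: direction indeterminate, fold to 0
      coh[stroma] <- 0
    } else {
      d <- .cpp_edt(!stroma)
      d <- gaussianSmooth(d, sigmaPx)
      H <- nrow(d); W <- ncol(d)
      gx <- (d[, pmin(seq_len(W) + 1L, W)] - d[, pmax(seq_len(W) - 1L, 1L)]) / 2
      gy <- (d[pmin(seq_len(H) + 1L, H), ] - d[pmax(seq_len(H) - 1L, 1L), ]) / 2
      th <- atan2(gy, gx) * 180 / pi + 90  # tangent = gradient rotated 90
      g2 <- gx^2 + gy^2
      th[g2 < 1e-12] <- 0                  # ridge points: indeterminate
      ang[stroma] <- foldAngle(th[stroma])
      coh[stroma] <- pmin(1, sqrt(g2[stroma]))
    }
  }
  new("OrientationMap", angleDeg = ang, coherence = coh, windowPx = 1L,
      pixelSizeUm = label@pixelSizeUm)
}
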