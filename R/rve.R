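#' @include AllClasses.R utils.R fabric.R orientation.R
NULL

# largest centred square (pixels) that fits inside the rotated raster
maxInscribedSquare <- function(W, H, angleDeg) {
  th <- angleDeg * pi / 180
  floor(min(W, H) / (abs(cos(th)) + abs(sin(th))))
}

#' Rotate a ROI to its fabric principal axes and crop a centred square
#'
#' Rotates the raster by \code{-angleDeg} (bringing the fabric major axis
#' onto direction 1) using nearest-neighbour sampling for both labels and
#' carried angles (labels are categorical; interpolation inventing new
#' labels would be a bug), then crops a centred square of
#' \code{outSizePx} pixels. Carried fibre angles are decremented by the
#' rotation angle (axial, mod 180). Exact multiples of 90 degrees are
#' handled as exact raster rotations.
#'
#' @param label a \linkS4class{LabelImage}
#' @param orientation optional \linkS4class{OrientationMap} to co-transform
#' @param angleDeg fabric principal angle to rotate away (degrees)
#' @param outSizePx output square size (pixels)
#' @return list with \code{label} and (when given) \code{orientation}
#' @export
rotateAndCrop <- function(label, orientation = NULL, angleDeg = 0,
                          outSizePx) {
  stopifnot(is(label, "LabelImage"))
  lab <- label@labels
  H <- nrow(lab); W <- ncol(lab)
  outSizePx <- as.integer(outSizePx)
  maxS <- maxInscribedSquare(W, H, angleDeg)
  if (outSizePx > maxS)
    stop("crop of ", outSizePx, " px exceeds the inscribed region; ",
         "maximal admissible size is ", maxS, " px")
  ang <- if (!is.null(orientation)) orientation@angleDeg else NULL
  coh <- if (!is.null(orientation)) orientation@coherence else NULL

  if (abs(angleDeg %% 90) < 1e-12) {
    k <- as.integer(round(-angleDeg / 90))
    labR <- rot90Raster(lab, k)
    if (!is.null(ang)) { ang <- rot90Raster(ang, k); coh <- rot90Raster(coh, k) }
  } else {
    th <- -angleDeg * pi / 180             # rotation applied to the content
    ct <- cos(th); st <- sin(th)
    cxS <- W / 2; cyS <- H / 2
    ## inverse map: source = R(+angle) (dest - centre) + centre
    jD <- matrix(rep(seq_len(W) - 0.5 - cxS, each = H), H, W)
    iD <- matrix(rep(seq_len(H) - 0.5 - cyS, W), H, W)
    xS <- ct * jD + st * iD + cxS          # R(-th) = R(angle)
    yS <- -st * jD + ct * iD + cyS
    jS <- pmin(pmax(ceiling(xS), 1L), W)
    iS <- pmin(pmax(ceiling(yS), 1L), H)
    idx <- cbind(as.vector(iS), as.vector(jS))
    labR <- matrix(lab[idx], H, W)
    if (!is.null(ang)) {
      angR <- matrix(ang[idx], H, W)
      cohR <- matrix(coh[idx], H, W)
      ang <- angR; coh <- cohR
    }
  }
  HR <- nrow(labR); WR <- ncol(labR)
  i0 <- floor((HR - outSizePx) / 2)
  j0 <- floor((WR - outSizePx) / 2)
  ir <- (i0 + 1):(i0 + outSizePx)
  jr <- (j0 + 1):(j0 + outSizePx)
  outLab <- labelImage(labR[ir, jr, drop = FALSE], label@pixelSizeUm)
  out <- list(label = outLab)
  if (!is.null(orientation)) {
    a <- foldAngle(ang[ir, jr, drop = FALSE] - angleDeg)
    a[outLab@labels != 0L] <- NA_real_
    ch <- coh[ir, jr, drop = FALSE]
    ch[outLab@labels != 0L] <- NA_real_
    out$orientation <- new("OrientationMap", angleDeg = a, coherence = ch,
                           windowPx = orientation@windowPx,
                           pixelSizeUm = orientation@pixelSizeUm)
  }
  out
}

#' Verify principal alignment after rotation and cropping
#'
#' Re-runs the MIL fabric analysis on a (rotated, cropped) image and returns
#' the absolute principal angle, which should not exceed the stated
#' allowance of 2 degrees for a correctly aligned ROI. An isotropic fabric
#' (arbitrary angle) passes with a note.
#'
#' @param label the cropped \linkS4class{LabelImage}
#' @param phase constituent to analyse
#' @param tolDeg allowance in degrees (default 2)
#' @param isoTol fabric with DA at or below this is treated as isotropic
#'   (its principal direction is not meaningful) and passes with a note
#' @param ... passed to \code{\link{fabricAnalysis}}
#' @return deviation in degrees with attributes \code{pass} and \code{note}
#' @export
verifyPrincipalAlignment <- function(label, phase = "stroma", tolDeg = 2,
                                     isoTol = 0.05, ...) {
  fr <- fabricAnalysis(label, phase = phase, ...)
  pa <- principalAngle(fr@fit)
  if (isTRUE(attr(pa, "arbitrary")) || fr@DA <= isoTol) {
    dev <- 0
    attr(dev, "pass") <- TRUE
    attr(dev, "note") <- "isotropic fabric - angle arbitrary"
    return(dev)
  }
  dev <- abs(as.numeric(pa))
  attr(dev, "pass") <- dev <= tolDeg
  attr(dev, "note") <- ""
  dev
}

#' Mirror a square ROI into a perfectly orthotropic periodic RVE
#'
#' The N x N input M becomes the 2N x 2N cell
#' [M | flip_x(M); flip_y(M) | flip_x(flip_y(M))] (quadrants listed bottom
#' row first). Mirroring forces exact equality of opposite boundary rows and
#' columns (periodicity) and mirror symmetry about both centre lines
#' (orthotropy), and preserves area fractions exactly. Axial fibre angles
#' transform as theta -> -theta under either single reflection and are
#' unchanged under the double reflection.
#'
#' @param label a square \linkS4class{LabelImage}
#' @param orientation optional matching \linkS4class{OrientationMap}
#' @param provenance optional list recorded in the result
#' @return a \linkS4class{PeriodicRVE}
#' @export
mirrorOrthotropic <- function(label, orientation = NULL,
                              provenance = list()) {
  stopifnot(is(label, "LabelImage"))
  M <- label@labels
  N <- nrow(M)
  if (ncol(M) != N) stop("mirroring requires a square input")
  fx <- function(m) m[, ncol(m):1, drop = FALSE]   # reflect about x = L
  fy <- function(m) m[nrow(m):1, , drop = FALSE]   # reflect about y = L
  big <- rbind(cbind(M, fx(M)), cbind(fy(M), fx(fy(M))))
  lab2 <- labelImage(big, label@pixelSizeUm)
  orient2 <- NULL
  if (!is.null(orientation)) {
    A <- orientation@angleDeg
    Ch <- orientation@coherence
    negA <- foldAngle(-A)
    bigA <- rbind(cbind(A, fx(negA)), cbind(fy(negA), fx(fy(A))))
    bigC <- rbind(cbind(Ch, fx(Ch)), cbind(fy(Ch), fx(fy(Ch))))
    orient2 <- new("OrientationMap", angleDeg = bigA, coherence = bigC,
                   windowPx = orientation@windowPx,
                   pixelSizeUm = orientation@pixelSizeUm)
  }
  new("PeriodicRVE", labels = lab2, orientation = orient2,
      provenance = provenance)
}

#' Check opposite-edge label periodicity of a raster
#'
#' @param label a \linkS4class{LabelImage}
#' @return list with \code{ok} and a data.frame \code{mismatches} of
#'   offending pixel pairs
#' @export
verifyPeriodicity <- function(label) {
  stopifnot(is(label, "LabelImage"))
  m <- label@labels
  H <- nrow(m); W <- ncol(m)
  mm <- list()
  lr <- which(m[, 1] != m[, W])
  if (length(lr))
    mm$lr <- data.frame(edge = "left-right", index = lr,
                        a = m[lr, 1], b = m[lr, W])
  bt <- which(m[1, ] != m[H, ])
  if (length(bt))
    mm$bt <- data.frame(edge = "bottom-top", index = bt,
                        a = m[1, bt], b = m[H, bt])
  mismatches <- if (length(mm)) do.call(rbind, mm) else
    data.frame(edge = character(), index = integer(),
               a = integer(), b = integer())
  list(ok = nrow(mismatches) == 0L, mismatches = mismatches)
}
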