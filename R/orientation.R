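#' @include AllClasses.R utils.R
NULL

#' Local fibre orientation by windowed structure-tensor analysis
#'
#' The stromal phase is divided into non-overlapping square sub-regions
#' (windows). In each window the 2 x 2 gradient structure tensor of the
#' stroma indicator, smoothed at scale \code{sigmaPx}, is accumulated over
#' the stromal pixels of the window. The dominant axial orientation is the
#' eigenvector of the smaller eigenvalue (along edges and stromal channels),
#' and the coherence is (lmax - lmin) / (lmax + lmin), defined as 0 when
#' both eigenvalues vanish. Windows with fewer than 25 % stromal pixels
#' inherit the orientation of the nearest valid window (ties broken by
#' row-major window order).
#'
#' @param label a \linkS4class{LabelImage} with stroma present
#' @param windowPx sub-region size in pixels (>= 4); the default 32 px is a
#'   scale well below typical stromal channel lengths
#' @param sigmaPx Gaussian smoothing scale of the indicator (pixels)
#' @return an \linkS4class{OrientationMap} (values constant per window,
#'   defined on the stromal support)
#' @export
localOrientationMap <- function(label, windowPx = 32L, sigmaPx = 1.5) {
  stopifnot(is(label, "LabelImage"))
  windowPx <- as.integer(windowPx)
  if (windowPx < 4L) stop("windowPx must be >= 4")
  stroma <- label@labels == 0L
  if (!any(stroma)) stop("no stromal pixels")
  ind <- gaussianSmooth(stroma * 1, sigmaPx)
  H <- nrow(ind); W <- ncol(ind)
  ## Scharr gradients (rotationally accurate): derivative [-1 0 1]/2 along
  ## one axis, smoothing [3 10 3]/16 along the other
  shx <- function(m, d) m[, pmin(pmax(seq_len(ncol(m)) + d, 1L), ncol(m))]
  shy <- function(m, d) m[pmin(pmax(seq_len(nrow(m)) + d, 1L), nrow(m)), ]
  dx <- (shx(ind, 1L) - shx(ind, -1L)) / 2
  gx <- (3 * shy(dx, 1L) + 10 * dx + 3 * shy(dx, -1L)) / 16
  dy <- (shy(ind, 1L) - shy(ind, -1L)) / 2
  gy <- (3 * shx(dy, 1L) + 10 * dy + 3 * shx(dy, -1L)) / 16
  ## one-sided differences on the frame are direction-biased: drop them
  gx[c(1L, H), ] <- 0; gx[, c(1L, W)] <- 0
  gy[c(1L, H), ] <- 0; gy[, c(1L, W)] <- 0
  jxx <- gx * gx; jyy <- gy * gy; jxy <- gx * gy

  nwr <- ceiling(H / windowPx)
  nwc <- ceiling(W / windowPx)
  wAng <- matrix(NA_real_, nwr, nwc)
  wCoh <- matrix(NA_real_, nwr, nwc)
  valid <- matrix(FALSE, nwr, nwc)
  for (wi in seq_len(nwr)) {
    ir <- (((wi - 1L) * windowPx + 1L):min(wi * windowPx, H))
    for (wj in seq_len(nwc)) {
      jr <- (((wj - 1L) * windowPx + 1L):min(wj * windowPx, W))
      sm <- stroma[ir, jr, drop = FALSE]
      if (mean(sm) < 0.25) next
      Jxx <- sum(jxx[ir, jr][sm]); Jyy <- sum(jyy[ir, jr][sm])
      Jxy <- sum(jxy[ir, jr][sm])
      tr <- Jxx + Jyy
      dd <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
      ## gradient-dominant direction; channel orientation is orthogonal
      thG <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
      wAng[wi, wj] <- foldAngle(thG + 90)
      wCoh[wi, wj] <- if (tr > 0) dd / tr else 0
      valid[wi, wj] <- TRUE
    }
  }
  if (!any(valid)) stop("no window with at least 25% stromal pixels")
  ## stroma-poor windows inherit the nearest valid window's angle
  if (any(!valid)) {
    vIdx <- which(valid, arr.ind = TRUE)
    for (lin in which(!t(valid))) {      # t() => row-major scan order
      wj <- (lin - 1L) %% nwc + 1L
      wi <- (lin - 1L) %/% nwc + 1L
      d2 <- (vIdx[, 1] - wi)^2 + (vIdx[, 2] - wj)^2
      ord <- order(d2, (vIdx[, 1] - 1) * nwc + vIdx[, 2]) # tie: row-major
      src <- vIdx[ord[1], ]
      wAng[wi, wj] <- wAng[src[1], src[2]]
      wCoh[wi, wj] <- wCoh[src[1], src[2]]
    }
  }
  ## expand to the pixel grid, restricted to the stromal support
  rowW <- pmin((seq_len(H) - 1L) %/% windowPx + 1L, nwr)
  colW <- pmin((seq_len(W) - 1L) %/% windowPx + 1L, nwc)
  ang <- wAng[rowW, colW, drop = FALSE]
  coh <- wCoh[rowW, colW, drop = FALSE]
  ang[!stroma] <- NA_real_
  coh[!stroma] <- NA_real_
  m <- new("OrientationMap", angleDeg = ang, coherence = coh,
           windowPx = windowPx, pixelSizeUm = label@pixelSizeUm)
  attr(m@angleDeg, "windowAngles") <- wAng
  m
}

# Window-level angle lookup at physical coordinates, ignoring per-pixel
# support (used by the mesher so every stromal element receives an angle).
windowAngleAt <- function(map, xUm, yUm) {
  px <- map@pixelSizeUm
  H <- nrow(map@angleDeg); W <- ncol(map@angleDeg)
  j <- pmin(pmax(ceiling(xUm / px), 1L), W)
  i <- pmin(pmax(ceiling(yUm / px), 1L), H)
  wA <- attr(map@angleDeg, "windowAngles")
  if (is.null(wA)) {
    a <- map@angleDeg[cbind(i, j)]
    return(a)
  }
  nwr <- nrow(wA); nwc <- ncol(wA)
  wi <- pmin((i - 1L) %/% map@windowPx + 1L, nwr)
  wj <- pmin((j - 1L) %/% map@windowPx + 1L, nwc)
  wA[cbind(wi, wj)]
}

#' Query the orientation map at a physical point
#'
#' Returns the angle of the window containing the point; NA for a
#' non-stromal query point. Querying outside the raster is an error.
#'
#' @param map an \linkS4class{OrientationMap}
#' @param xUm,yUm physical coordinates (um, origin at the lower-left corner)
#' @return angle in degrees, or NA for a non-stromal location
#' @export
elementOrientation <- function(map, xUm, yUm) {
  stopifnot(is(map, "OrientationMap"))
  px <- map@pixelSizeUm
  H <- nrow(map@angleDeg); W <- ncol(map@angleDeg)
  if (any(xUm < 0 | xUm > W * px | yUm < 0 | yUm > H * px))
    stop("query point outside raster")
  j <- pmin(pmax(ceiling(xUm / px), 1L), W)
  i <- pmin(pmax(ceiling(yUm / px), 1L), H)
  map@angleDeg[cbind(i, j)]
}
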