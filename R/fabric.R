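#' @include AllClasses.R utils.R
NULL

#' Mean intercept lengths of a binary mask
#'
#' For each sampling direction (\code{nDirections} values uniform on
#' [0, 180) plus one shared random rotational offset drawn from the seed),
#' parallel test lines at the given spacing are laid across the raster. The
#' mean intercept length is the total foreground length traversed divided by
#' the number of foreground runs intersected (the BoneJ-style run-based
#' convention, interfaces counted at label transitions). The cloud holds
#' MIL(theta) * (cos theta, sin theta) and its antipode, in micrometres.
#'
#' A full-foreground mask has no interfaces: each line contributes a single
#' run, so MIL(theta) equals the mean chord length and the cloud is flagged
#' degenerate. An empty mask is an error.
#'
#' @param mask logical matrix, or a \linkS4class{LabelImage} with
#'   \code{phase}
#' @param nDirections number of sampling directions (>= 8)
#' @param lineSpacingPx spacing of the parallel lines in pixels
#' @param seed integer seed for the shared angular offset
#' @param phase constituent to extract when \code{mask} is a LabelImage
#' @param pixelSizeUm pixel size when \code{mask} is a bare matrix
#' @return a \linkS4class{MILPointCloud}
#' @export
meanInterceptLengths <- function(mask, nDirections = 180L,
                                 lineSpacingPx = 1, seed = 1L,
                                 phase = "stroma", pixelSizeUm = 1) {
  if (is(mask, "LabelImage")) {
    pixelSizeUm <- mask@pixelSizeUm
    mask <- phaseMask(mask, phase)
  }
  stopifnot(is.matrix(mask), is.logical(mask))
  nDirections <- as.integer(nDirections)
  if (nDirections < 8L) stop("nDirections must be >= 8")
  if (!any(mask)) stop("empty-foreground mask: MIL undefined")
  degenerate <- all(mask)
  set.seed(as.integer(seed))
  offset <- stats::runif(1, 0, pi / nDirections)
  theta <- offset + (seq_len(nDirections) - 1L) * pi / nDirections
  res <- .cpp_mil(mask, theta, lineSpacingPx, 0.5)
  runs <- res[, 2]
  ok <- runs > 0
  mil <- res[ok, 1] / runs[ok] * pixelSizeUm
  th <- theta[ok]
  pts <- cbind(mil * cos(th), mil * sin(th))
  pts <- rbind(pts, -pts)
  new("MILPointCloud", points = pts, directionsUsed = nDirections,
      lineSpacingPx = lineSpacingPx, seed = as.integer(seed),
      degenerate = degenerate)
}

#' Fit an origin-centred ellipse to a MIL point cloud
#'
#' Least squares on the quadratic form x' Q x = 1 over the cloud (clouds are
#' antipodally symmetric by construction, so the ellipse is origin-centred
#' and the fit reduces to a symmetric 2 x 2 form). Radii derive from the
#' eigenvalues of Q: a = lmax^(-1/2) <= b = lmin^(-1/2), and the major-axis
#' angle is the eigenvector direction of lmin. A collinear (rank-deficient)
#' cloud yields the degenerate fit a = 0 with the major axis along the
#' points.
#'
#' @param cloud a \linkS4class{MILPointCloud} with >= 8 points
#' @return an \linkS4class{EllipseFit}
#' @export
fitEllipse <- function(cloud) {
  stopifnot(is(cloud, "MILPointCloud"))
  p <- cloud@points
  if (nrow(p) < 8) stop("need at least 8 points")
  x <- p[, 1]; y <- p[, 2]
  ## design for q = (Q11, Q22, Q12): x^2 q1 + y^2 q2 + 2xy q3 = 1
  A <- cbind(x^2, y^2, 2 * x * y)
  AtA <- crossprod(A)
  sv <- svd(AtA)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < 3) {
    ## collinear cloud through the origin: direction of the line
    v1 <- svd(cbind(x, y))$v[, 1]
    b <- max(sqrt(x^2 + y^2))
    angle <- foldAngle(atan2(v1[2], v1[1]) * 180 / pi)
    return(ellipseFit(0, b, angle, isotropic = FALSE, degenerate = TRUE))
  }
  q <- solve(AtA, crossprod(A, rep(1, nrow(A))))
  Q <- matrix(c(q[1], q[3], q[3], q[2]), 2, 2)
  e <- eigen(Q, symmetric = TRUE)
  if (any(e$values <= 0)) {
    ## not an ellipse (pathological cloud): treat as degenerate
    v1 <- e$vectors[, which.min(e$values)]
    b <- max(sqrt(x^2 + y^2))
    return(ellipseFit(0, b, foldAngle(atan2(v1[2], v1[1]) * 180 / pi),
                      degenerate = TRUE))
  }
  a <- 1 / sqrt(max(e$values))          # minor radius
  b <- 1 / sqrt(min(e$values))          # major radius
  vmaj <- e$vectors[, which.min(e$values)]
  angle <- foldAngle(atan2(vmaj[2], vmaj[1]) * 180 / pi)
  iso <- (b - a) <= 1e-9 * b
  if (iso) angle <- 0
  ellipseFit(a, b, angle, isotropic = iso)
}

#' Degree of anisotropy of a fitted MIL ellipse
#'
#' DA = 1 - a^2/b^2: 0 for structural isotropy (a = b), 1 for full
#' anisotropy (a = 0).
#'
#' @param fit an \linkS4class{EllipseFit} with b > 0
#' @return DA in [0, 1]
#' @export
degreeOfAnisotropy <- function(fit) {
  stopifnot(is(fit, "EllipseFit"))
  if (fit@bUm <= 0) stop("degenerate fit with b = 0: DA undefined")
  1 - fit@aUm^2 / fit@bUm^2
}

#' Principal (major-axis) angle of a fabric ellipse
#'
#' Angle in [-90, 90); an isotropic fit (a = b) reports 0 with the
#' "arbitrary" attribute set.
#'
#' @param fit an \linkS4class{EllipseFit}
#' @return angle in degrees with attribute \code{arbitrary}
#' @export
principalAngle <- function(fit) {
  stopifnot(is(fit, "EllipseFit"))
  a <- foldAngle(fit@angleDeg)
  attr(a, "arbitrary") <- isTRUE(fit@isotropic)
  a
}

#' One-call MIL fabric analysis of a constituent
#'
#' @param label a \linkS4class{LabelImage}
#' @param phase constituent name or id
#' @param nDirections,lineSpacingPx,seed passed to
#'   \code{\link{meanInterceptLengths}}
#' @return a \linkS4class{FabricResult}
#' @export
fabricAnalysis <- function(label, phase = "stroma", nDirections = 180L,
                           lineSpacingPx = 1, seed = 1L) {
  cloud <- meanInterceptLengths(label, nDirections = nDirections,
                                lineSpacingPx = lineSpacingPx, seed = seed,
                                phase = phase)
  fit <- fitEllipse(cloud)
  new("FabricResult", fit = fit, DA = degreeOfAnisotropy(fit))
}
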