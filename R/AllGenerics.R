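#' @include AllClasses.R
NULL

#' Accessors for raster containers
#'
#' \code{labels()} returns the integer label raster, \code{pixelSize()} the
#' physical pixel size in micrometres, \code{angles()} / \code{coherence()}
#' the orientation-map rasters.
#'
#' @param object a package object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labels")

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("coherence", function(object) standardGeneric("coherence"))

#' @rdname accessors
#' @export
setMethod("labels", "LabelImage", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "LabelImage", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("pixelSize", "GreyImage", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("pixelSize", "OrientationMap", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("angles", "OrientationMap", function(object) object@angleDeg)

#' @rdname accessors
#' @export
setMethod("coherence", "OrientationMap", function(object) object@coherence)

#' @rdname accessors
#' @export
setMethod("labels", "PeriodicRVE", function(object) object@labels@labels)

#' @rdname accessors
#' @export
setMethod("dim", "LabelImage", function(x) dim(x@labels))

#' @rdname accessors
#' @export
setMethod("dim", "GreyImage", function(x) dim(x@intensities))

#' Fabric accessors
#'
#' @param object an \linkS4class{EllipseFit} or \linkS4class{FabricResult}
#' @name fabric-accessors
NULL

#' @rdname fabric-accessors
#' @export
setGeneric("minorRadius", function(object) standardGeneric("minorRadius"))

#' @rdname fabric-accessors
#' @export
setGeneric("majorRadius", function(object) standardGeneric("majorRadius"))

#' @rdname fabric-accessors
#' @export
setMethod("minorRadius", "EllipseFit", function(object) object@aUm)

#' @rdname fabric-accessors
#' @export
setMethod("majorRadius", "EllipseFit", function(object) object@bUm)

#' @rdname fabric-accessors
#' @export
setMethod("minorRadius", "FabricResult", function(object) object@fit@aUm)

#' @rdname fabric-accessors
#' @export
setMethod("majorRadius", "FabricResult", function(object) object@fit@bUm)

setMethod("show", "LabelImage", function(object) {
  d <- dim(object@labels)
  fr <- areaFractions(object)
  cat(sprintf("LabelImage %d x %d px (%.3g um/px)\n", d[2], d[1],
              object@pixelSizeUm))
  cat(sprintf("  fractions: stroma %.3f, epithelium %.3f, lumen %.3f\n",
              fr[1], fr[2], fr[3]))
})

setMethod("show", "OrientationMap", function(object) {
  n <- sum(!is.na(object@angleDeg))
  cat(sprintf("OrientationMap %d x %d px, window %d px, %d stromal px\n",
              ncol(object@angleDeg), nrow(object@angleDeg),
              object@windowPx, n))
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf("EllipseFit a = %.4g um, b = %.4g um, angle = %.2f deg%s\n",
              object@aUm, object@bUm, object@angleDeg,
              if (object@isotropic) " (isotropic - angle arbitrary)" else ""))
})

setMethod("show", "FabricResult", function(object) {
  show(object@fit)
  cat(sprintf("  DA = %.4f\n", object@DA))
})

setMethod("show", "MILPointCloud", function(object) {
  cat(sprintf("MILPointCloud: %d points, %d directions, spacing %.2g px%s\n",
              nrow(object@points), object@directionsUsed,
              object@lineSpacingPx,
              if (object@degenerate) " (degenerate: full foreground)" else ""))
})

setMethod("show", "PeriodicRVE", function(object) {
  d <- dim(object@labels@labels)
  cat(sprintf("PeriodicRVE %d x %d px (mirrored, exactly periodic)\n",
              d[2], d[1]))
})

setMethod("show", "FEModel", function(object) {
  cat(sprintf("FEModel: %d x %d bilinear quads, h = %.3g um, %d nodes\n",
              object@nx, object@ny, object@hUm,
              (object@nx + 1L) * (object@ny + 1L)))
})

setMethod("show", "ApparentModuli", function(object) {
  cat("ApparentModuli (kPa):\n")
  cat(sprintf("  E11: %.3f (t) / %.3f (c)\n", object@E11t, object@E11c))
  cat(sprintf("  E22: %.3f (t) / %.3f (c)\n", object@E22t, object@E22c))
  cat(sprintf("  G12: %.3f (t) / %.3f (c)\n", object@G12t, object@G12c))
})

setMethod("show", "NeoHookean", function(object) {
  cat(sprintf("NeoHookean: C10 = %.4g kPa, D1 = %.4g 1/kPa\n",
              object@C10, object@D1))
})

setMethod("show", "HGO", function(object) {
  cat(sprintf(
    "HGO: C10 = %.4g kPa, D1 = %.4g 1/kPa, k1 = %.4g kPa, k2 = %.4g, kappa = %.4g\n",
    object@C10, object@D1, object@k1, object@k2, object@kappa))
})
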