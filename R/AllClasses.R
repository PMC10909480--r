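#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib HistoMech, .registration = TRUE
NULL

LABEL_STROMA     <- 0L
LABEL_EPITHELIUM <- 1L
LABEL_LUMEN      <- 2L
LABEL_NAMES <- c(stroma = 0L, epithelium = 1L, lumen = 2L)

#' LabelImage: segmented three-phase microstructure raster
#'
#' Integer raster with one label per pixel: 0 = stroma, 1 = epithelial
#' compartment, 2 = acinar lumen, plus a physical pixel size in micrometres.
#' The raster is stored with row index increasing upwards, so that element
#' \code{[i, j]} has pixel-centre physical coordinates
#' \code{((j - 0.5) * pixelSize, (i - 0.5) * pixelSize)} with the origin at
#' the lower-left image corner. Angles are measured in degrees,
#' counter-clockwise from the x-axis (direction 1), folded to [-90, 90).
#'
#' @slot labels integer matrix with values in \{0, 1, 2\}
#' @slot pixelSizeUm positive numeric, micrometres per pixel
#' @export
setClass("LabelImage",
  representation(labels = "matrix", pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@labels) && !is.integer(object@labels))
      msg <- c(msg, "labels must be an integer matrix")
    bad <- setdiff(unique(as.vector(object@labels)), c(0L, 1L, 2L))
    if (length(bad))
      msg <- c(msg, sprintf("unknown label %s", paste(bad, collapse = ", ")))
    if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelImage
#'
#' @param labels integer matrix (0 = stroma, 1 = epithelium, 2 = lumen)
#' @param pixelSizeUm pixel size in micrometres
#' @return a \linkS4class{LabelImage}
#' @export
labelImage <- function(labels, pixelSizeUm) {
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' GreyImage: intensity raster in [0, 1]
#'
#' @slot intensities numeric matrix with finite values in [0, 1]
#' @slot pixelSizeUm positive numeric
#' @export
setClass("GreyImage",
  representation(intensities = "matrix", pixelSizeUm = "numeric"),
  validity = function(object) {
    v <- object@intensities
    if (!all(is.finite(v))) return("intensities must be finite")
    if (any(v < 0 | v > 1)) return("intensities must lie in [0, 1]")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
    TRUE
  })

#' @rdname GreyImage-class
#' @param intensities numeric matrix in [0, 1]
#' @param pixelSizeUm pixel size in micrometres
#' @export
greyImage <- function(intensities, pixelSizeUm) {
  new("GreyImage", intensities = intensities,
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' OrientationMap: per-pixel axial fibre angles on the stromal support
#'
#' Angles are axial (theta and theta + 180 are identified), in degrees in
#' [-90, 90), defined on stromal pixels and NA elsewhere. Coherence in [0, 1]
#' measures how anisotropic the local structure tensor is.
#'
#' @slot angleDeg numeric matrix, NA off the stromal support
#' @slot coherence numeric matrix in [0, 1] (NA off support)
#' @slot windowPx sub-region size used for estimation (pixels)
#' @slot pixelSizeUm physical pixel size
#' @export
setClass("OrientationMap",
  representation(angleDeg = "matrix", coherence = "matrix",
                 windowPx = "integer", pixelSizeUm = "numeric"),
  validity = function(object) {
    a <- object@angleDeg
    if (!identical(dim(a), dim(object@coherence)))
      return("angle and coherence rasters must have identical shape")
    ok <- is.na(a) | (a >= -90 & a < 90)
    if (!all(ok)) return("angles must lie in [-90, 90)")
    ch <- object@coherence
    if (any(!is.na(ch) & (ch < 0 | ch > 1)))
      return("coherence must lie in [0, 1]")
    if (object@windowPx < 1L) return("windowPx must be positive")
    TRUE
  })

#' MILPointCloud: mean-intercept-length vectors for a set of directions
#'
#' Each sampling direction theta contributes the point MIL(theta) *
#' (cos theta, sin theta) and its antipode, in micrometres.
#'
#' @slot points n x 2 numeric matrix (um), closed under negation
#' @slot directionsUsed number of sampling directions
#' @slot lineSpacingPx spacing of the parallel test lines (pixels)
#' @slot seed integer seed that drew the shared angular offset
#' @slot degenerate TRUE when the mask was full-foreground (zero interfaces)
#' @export
setClass("MILPointCloud",
  representation(points = "matrix", directionsUsed = "integer",
                 lineSpacingPx = "numeric", seed = "integer",
                 degenerate = "logical"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2) return("points must be n x 2")
    if (!all(is.finite(p))) return("points must be finite")
    TRUE
  })

#' EllipseFit: origin-centred ellipse fitted to a MIL point cloud
#'
#' @slot aUm minor radius (um), may be 0 for a degenerate collinear cloud
#' @slot bUm major radius (um)
#' @slot angleDeg major-axis direction in [-90, 90)
#' @slot isotropic TRUE when a == b so the angle is arbitrary
#' @slot degenerate TRUE for a rank-deficient (collinear) cloud
#' @export
setClass("EllipseFit",
  representation(aUm = "numeric", bUm = "numeric", angleDeg = "numeric",
                 isotropic = "logical", degenerate = "logical"),
  validity = function(object) {
    if (object@aUm < 0) return("a must be >= 0")
    if (object@aUm > object@bUm + 1e-12 * max(1, object@bUm))
      return("requires a <= b")
    if (object@angleDeg < -90 || object@angleDeg >= 90)
      return("angle must lie in [-90, 90)")
    TRUE
  })

ellipseFit <- function(aUm, bUm, angleDeg, isotropic = FALSE,
                       degenerate = FALSE) {
  new("EllipseFit", aUm = aUm, bUm = bUm, angleDeg = angleDeg,
      isotropic = isotropic, degenerate = degenerate)
}

#' FabricResult: MIL fabric ellipse plus degree of anisotropy
#'
#' DA = 1 - a^2/b^2; 0 indicates structural isotropy, 1 full anisotropy.
#'
#' @slot fit the fitted \linkS4class{EllipseFit}
#' @slot DA degree of anisotropy in [0, 1]
#' @export
setClass("FabricResult",
  representation(fit = "EllipseFit", DA = "numeric"),
  validity = function(object) {
    da <- 1 - object@fit@aUm^2 / object@fit@bUm^2
    if (abs(object@DA - da) > 1e-9)
      return("DA must equal 1 - a^2/b^2 of the stored fit")
    TRUE
  })

#' PeriodicRVE: mirrored, exactly periodic orthotropic cell
#'
#' @slot labels mirrored \linkS4class{LabelImage} (2N x 2N)
#' @slot orientation matching \linkS4class{OrientationMap} (may be empty)
#' @slot provenance list: source id, rotation angle, crop window,
#'   principal-axis re-check deviation
#' @export
setClass("PeriodicRVE",
  representation(labels = "LabelImage", orientation = "ANY",
                 provenance = "list"))

#' FEModel: structured bilinear-quad mesh derived from a pixel raster
#'
#' One square element per pixel block; node id = iy * (nx + 1) + ix + 1 with
#' ix fastest (x to the right, y upwards). Element connectivity is
#' counter-clockwise.
#'
#' @slot nx,ny element counts along x and y
#' @slot hUm element edge length (um)
#' @slot elemLabel integer vector (0/1/2) per element
#' @slot elemAngleDeg fibre angle per element (NA for non-stromal)
#' @export
setClass("FEModel",
  representation(nx = "integer", ny = "integer", hUm = "numeric",
                 elemLabel = "integer", elemAngleDeg = "numeric"),
  validity = function(object) {
    if (length(object@elemLabel) != object@nx * object@ny)
      return("elemLabel length must be nx * ny")
    if (length(object@elemAngleDeg) != object@nx * object@ny)
      return("elemAngleDeg length must be nx * ny")
    st <- object@elemLabel == 0L
    if (any(st & !is.finite(object@elemAngleDeg)))
      return("every stromal element needs a defined fibre angle")
    TRUE
  })

#' PBCConstraints: periodic node pairings and macro reference DOFs
#'
#' @slot pairs data.frame with columns slave, master (node ids) and the
#'   reference offset dx, dy (um)
#' @slot pinned node id fixed to zero displacement (kills rigid translation)
#' @slot nNodes total node count of the mesh
#' @export
setClass("PBCConstraints",
  representation(pairs = "data.frame", pinned = "integer",
                 nNodes = "integer"))

#' MacroLoadCase: one homogenization test
#'
#' @slot kind one of "uniaxial-1", "uniaxial-2", "shear-12"
#' @slot sign +1 (tension / positive shear) or -1
#' @slot magnitude global test strain (default 0.05, engineering)
#' @export
setClass("MacroLoadCase",
  representation(kind = "character", sign = "numeric",
                 magnitude = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("uniaxial-1", "uniaxial-2", "shear-12"))
      return("kind must be uniaxial-1, uniaxial-2 or shear-12")
    if (!object@sign %in% c(-1, 1)) return("sign must be +1 or -1")
    if (object@magnitude < 0) return("magnitude must be nonnegative")
    TRUE
  })

#' @rdname MacroLoadCase-class
#' @param kind,sign,magnitude see slots
#' @export
macroLoadCase <- function(kind, sign = 1, magnitude = 0.05) {
  new("MacroLoadCase", kind = kind, sign = as.numeric(sign),
      magnitude = magnitude)
}

#' ApparentModuli: six secant moduli of an RVE
#'
#' Secant moduli at the full test strain: E11 and E22 under tension (t) and
#' compression (c) and the engineering shear modulus G12 for both shear
#' signs, all in kPa.
#'
#' @slot E11t,E11c,E22t,E22c,G12t,G12c numeric (kPa)
#' @export
setClass("ApparentModuli",
  representation(E11t = "numeric", E11c = "numeric", E22t = "numeric",
                 E22c = "numeric", G12t = "numeric", G12c = "numeric"))

#' Material parameter classes
#'
#' \code{NeoHookean} holds the compressible neo-Hookean pair (C10, D1);
#' \code{HGO} adds a single tension-only collagen fibre family
#' (k1, k2, kappa). Units are kPa for C10 and k1, 1/kPa for D1; k2 and kappa
#' are dimensionless with kappa in [0, 1/3] (0 = perfectly aligned fibres,
#' 1/3 = isotropic dispersion).
#'
#' @slot C10 matrix stiffness (kPa)
#' @slot D1 inverse-bulk parameter (1/kPa); small-strain bulk modulus 2/D1
#' @export
setClass("NeoHookean",
  representation(C10 = "numeric", D1 = "numeric"),
  validity = function(object) {
    if (object@C10 <= 0) return("C10 must be positive")
    if (object@D1 <= 0) return("D1 must be positive")
    TRUE
  })

#' @rdname NeoHookean-class
#' @slot k1 fibre stiffness (kPa)
#' @slot k2 dimensionless fibre nonlinearity
#' @slot kappa fibre dispersion in [0, 1/3]
#' @export
setClass("HGO", contains = "NeoHookean",
  representation(k1 = "numeric", k2 = "numeric", kappa = "numeric"),
  validity = function(object) {
    if (object@k1 < 0) return("k1 must be >= 0")
    if (object@k2 <= 0) return("k2 must be positive")
    if (object@kappa < 0 || object@kappa > 1 / 3)
      return("kappa must lie in [0, 1/3]")
    TRUE
  })

#' DeformationState: in-plane deformation gradient plus thickness stretch
#'
#' @slot F 2 x 2 in-plane deformation gradient (det > 0)
#' @slot lambda3 out-of-plane stretch (> 0)
#' @slot fiberAngleDeg axial fibre angle (NA for isotropic materials)
#' @export
setClass("DeformationState",
  representation(F = "matrix", lambda3 = "numeric",
                 fiberAngleDeg = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@F), c(2L, 2L))) return("F must be 2 x 2")
    if (det(object@F) <= 0) return("det(F) must be positive")
    if (object@lambda3 <= 0) return("lambda3 must be positive")
    TRUE
  })

#' @rdname DeformationState-class
#' @param F 2 x 2 deformation gradient
#' @param lambda3 out-of-plane stretch
#' @param fiberAngleDeg axial fibre angle in degrees (NA if unused)
#' @export
deformationState <- function(F, lambda3 = 1, fiberAngleDeg = NA_real_) {
  new("DeformationState", F = F, lambda3 = lambda3,
      fiberAngleDeg = as.numeric(fiberAngleDeg))
}

#' MicrostructureSpec: parameters of the synthetic three-phase generator
#'
#' @slot widthPx,heightPx raster size in pixels
#' @slot pixelSizeUm micrometres per pixel
#' @slot nAcini number of acini to place
#' @slot lumenRadiusMeanUm,lumenRadiusSdUm lumen semi-minor radius law (um)
#' @slot epitheliumThicknessUm epithelial ring thickness (um)
#' @slot elongation major/minor axis ratio of acini (>= 1)
#' @slot preferredAngleDeg mean acinus orientation in [-90, 90)
#' @slot angleDispersionDeg circular s.d. of acinus orientations (degrees)
#' @slot seed integer seed; identical spec + seed gives bit-identical output
#' @export
setClass("MicrostructureSpec",
  representation(widthPx = "integer", heightPx = "integer",
                 pixelSizeUm = "numeric", nAcini = "integer",
                 lumenRadiusMeanUm = "numeric", lumenRadiusSdUm = "numeric",
                 epitheliumThicknessUm = "numeric", elongation = "numeric",
                 preferredAngleDeg = "numeric",
                 angleDispersionDeg = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@widthPx < 1L || object@heightPx < 1L)
      msg <- c(msg, "raster size must be positive")
    if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
    if (object@nAcini < 0L) msg <- c(msg, "nAcini must be >= 0")
    if (object@lumenRadiusMeanUm <= 0 || object@lumenRadiusSdUm < 0)
      msg <- c(msg, "lumen radius law must be positive")
    if (object@epitheliumThicknessUm <= 0)
      msg <- c(msg, "epitheliumThicknessUm must be > 0")
    if (object@elongation < 1) msg <- c(msg, "elongation must be >= 1")
    if (object@preferredAngleDeg < -90 || object@preferredAngleDeg >= 90)
      msg <- c(msg, "preferredAngleDeg must lie in [-90, 90)")
    if (object@angleDispersionDeg < 0)
      msg <- c(msg, "angleDispersionDeg must be >= 0")
    # reject impossible packings up front
    area <- as.numeric(object@widthPx) * object@heightPx *
      object@pixelSizeUm^2
    rOut <- object@lumenRadiusMeanUm * object@elongation +
      object@epitheliumThicknessUm
    if (object@nAcini * pi * rOut^2 > area)
      msg <- c(msg, "infeasible spec: requested acini cannot fit the image")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: exact bookkeeping of a generated microstructure
#'
#' @slot areaFractions named numeric (stroma, epithelium, lumen) summing to 1
#' @slot centres n x 2 matrix of acinus centres (um)
#' @slot axes n x 2 matrix of lumen semi-axes (minor, major; um)
#' @slot angles acinus orientations (degrees)
#' @slot truePreferredAngleDeg the requested preferred angle
#' @export
setClass("GroundTruth",
  representation(areaFractions = "numeric", centres = "matrix",
                 axes = "matrix", angles = "numeric",
                 truePreferredAngleDeg = "numeric"),
  validity = function(object) {
    if (abs(sum(object@areaFractions) - 1) > 1e-12)
      return("area fractions must sum to 1")
    TRUE
  })
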