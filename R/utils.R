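#' @include AllClasses.R
NULL

# Fold an angle in degrees to the axial range [-90, 90).
foldAngle <- function(deg) ((deg + 90) %% 180) - 90

# Resolve a phase given as id (0/1/2) or name to an integer label.
resolvePhase <- function(phase) {
  if (is.character(phase)) {
    if (!phase %in% names(LABEL_NAMES))
      stop("unknown phase '", phase, "'")
    return(LABEL_NAMES[[phase]])
  }
  phase <- as.integer(phase)
  if (!phase %in% c(0L, 1L, 2L)) stop("unknown phase ", phase)
  phase
}

#' Binary mask of one tissue constituent
#'
#' @param label a \linkS4class{LabelImage}
#' @param phase label id (0/1/2) or name ("stroma", "epithelium", "lumen")
#' @return logical matrix, TRUE where the raster carries the phase
#' @export
phaseMask <- function(label, phase) {
  stopifnot(is(label, "LabelImage"))
  label@labels == resolvePhase(phase)
}

# Separable Gaussian smoothing with edge renormalization (NA-free input).
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) { # along rows (dimension 1)
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    wt <- matrix(0, n, ncol(x))
    for (d in -r:r) {
      src <- pmin(pmax(seq_len(n) + d, 1L), n) # replicate edges
      out <- out + k[d + r + 1] * x[src, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(m))))
}

# Number of 4-connected components of a logical mask.
nComponents <- function(mask) .cpp_n_components(mask)

# Rotate a matrix raster by an exact multiple of 90 degrees (CCW, in the
# physical frame where rows increase upwards).
rot90Raster <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  ## with rows increasing upwards, CCW by 90 maps m[i, j] so that
  ## m'[i', j'] = m[H + 1 - j', i']: reverse rows, then transpose.
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}
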