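#' @include AllClasses.R utils.R
NULL

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

fileExt <- function(path) tolower(tools::file_ext(path))

checkLossless <- function(path) {
  ext <- fileExt(path)
  if (ext %in% c("jpg", "jpeg"))
    stop("lossy format '", ext, "' rejected: use lossless PNG or TIFF")
  if (!ext %in% c("png", "tif", "tiff"))
    stop("unsupported raster format '", ext, "'")
  ext
}

#' Write a LabelImage to lossless PNG/TIFF with a JSON sidecar
#'
#' The raster is stored 8-bit with the raw label values 0/1/2; the sidecar
#' (same basename, .json) records the pixel size, label legend and any extra
#' metadata (e.g. a generator seed or spec echo).
#'
#' @param label a \linkS4class{LabelImage}
#' @param path output file ending in .png, .tif or .tiff
#' @param meta optional named list merged into the sidecar
#' @return invisibly, the sidecar path
#' @export
writeLabelImage <- function(label, path, meta = list()) {
  stopifnot(is(label, "LabelImage"))
  validObject(label)
  ext <- checkLossless(path)
  img <- label@labels[nrow(label@labels):1, , drop = FALSE] / 255
  if (ext == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 8L,
                       compression = "none")
  side <- c(list(pixel_size_um = label@pixelSizeUm,
                 legend = list(stroma = 0L, epithelium = 1L, lumen = 2L)),
            meta)
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecarPath(path))
}

#' Read a LabelImage written by \code{\link{writeLabelImage}}
#'
#' Round-trips bit-exactly with the writer. The pixel size is taken from the
#' JSON sidecar when present, otherwise from \code{pixelSizeUm}; missing
#' both is an error.
#'
#' @param path PNG/TIFF path
#' @param pixelSizeUm pixel size fallback when no sidecar exists
#' @return a \linkS4class{LabelImage}
#' @export
readLabelImage <- function(path, pixelSizeUm = NULL) {
  ext <- checkLossless(path)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (is.list(img)) img <- img[[1]]
  if (length(dim(img)) == 3) img <- img[, , 1]
  lab <- round(img * 255)
  bad <- setdiff(unique(as.vector(lab)), c(0, 1, 2))
  if (length(bad)) {
    idx <- which(lab == bad[1], arr.ind = TRUE)[1, ]
    stop(sprintf("unknown label %d at pixel (row %d, col %d)",
                 as.integer(bad[1]), idx[1], idx[2]))
  }
  ps <- pixelSizeUm
  sp <- sidecarPath(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp)
    if (!is.null(side$pixel_size_um)) ps <- side$pixel_size_um
  }
  if (is.null(ps))
    stop("pixel size unknown: provide a JSON sidecar or pixelSizeUm")
  labelImage(lab[nrow(lab):1, , drop = FALSE], as.numeric(ps))
}

#' Greyscale threshold segmentation into three phases
#'
#' Band assignment follows H&E appearance: the darkest band (hematoxylin-
#' dense) is the epithelial compartment, intermediate intensities are stroma,
#' and the brightest band is acinar lumen.
#'
#' @param grey a \linkS4class{GreyImage}
#' @param tLow,tHigh thresholds with 0 <= tLow < tHigh <= 1
#' @return a \linkS4class{LabelImage}
#' @export
thresholdSegment <- function(grey, tLow, tHigh) {
  stopifnot(is(grey, "GreyImage"))
  if (!(tLow >= 0 && tLow < tHigh && tHigh <= 1))
    stop("thresholds out of order: need 0 <= tLow < tHigh <= 1")
  v <- grey@intensities
  lab <- matrix(LABEL_STROMA, nrow(v), ncol(v))
  lab[v < tLow] <- LABEL_EPITHELIUM
  lab[v >= tHigh] <- LABEL_LUMEN
  labelImage(lab, grey@pixelSizeUm)
}

#' Serialize an OrientationMap as a float-TIFF pair plus JSON metadata
#'
#' Writes \code{<base>_angle.tif} and \code{<base>_coherence.tif} (32-bit
#' float, NaN off the stromal support) and \code{<base>.json}.
#'
#' @param map an \linkS4class{OrientationMap}
#' @param base output path prefix
#' @return invisibly, the JSON path
#' @export
writeOrientationMap <- function(map, base) {
  stopifnot(is(map, "OrientationMap"))
  flip <- function(m) m[nrow(m):1, , drop = FALSE]
  ## angles live in [-90, 90): map to [0, 1) and reserve exactly 1 for the
  ## undefined marker so the support survives the float round trip
  a <- (map@angleDeg + 90) / 180
  a[is.na(a)] <- 1
  ch <- map@coherence
  ch[is.na(ch)] <- 0
  tiff::writeTIFF(flip(a), paste0(base, "_angle.tif"),
                  bits.per.sample = 32L, compression = "none")
  tiff::writeTIFF(flip(ch), paste0(base, "_coherence.tif"),
                  bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(window_px = map@windowPx,
                            pixel_size_um = map@pixelSizeUm),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".json"))
}

#' @rdname writeOrientationMap
#' @param base output path prefix used at write time
#' @export
readOrientationMap <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"))
  flip <- function(m) m[nrow(m):1, , drop = FALSE]
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    if (is.list(m)) m <- m[[1]]
    flip(m)
  }
  a <- rd(paste0(base, "_angle.tif"))
  und <- a >= 1 - 1e-7
  ang <- a * 180 - 90
  ang[und] <- NA_real_
  ch <- rd(paste0(base, "_coherence.tif"))
  ch[und] <- NA_real_
  new("OrientationMap", angleDeg = ang, coherence = ch,
      windowPx = as.integer(meta$window_px),
      pixelSizeUm = as.numeric(meta$pixel_size_um))
}
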