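## Central S4 containers for the three measurement modalities.

.CONDITIONS <- c("Control", "MWD", "SWD")
.VIEWS <- c("top", "side")

#' RgbImage: a calibrated 2-D colour frame of one plant
#'
#' Holds an H x W x 3 array of 8-bit R,G,B intensities together with the
#' acquisition metadata used throughout the shoot-trait pipeline: camera
#' view (top or side), day after shoot emergence (DASE), optional spatial
#' calibration in mm per pixel, plant identifier and watering condition.
#' Channel order is fixed as R,G,B at the API boundary regardless of the
#' file dialect the pixels came from.
#'
#' @slot pixels numeric H x W x 3 array, values in [0, 255]
#' @slot view "top" or "side"
#' @slot dase integer day after shoot emergence
#' @slot scaleMmPerPx positive mm-per-pixel scale, or NA when uncalibrated
#' @slot plantId plant identifier
#' @slot condition watering condition: "Control", "MWD" or "SWD"
#' @aliases RgbImage-class
#' @exportClass RgbImage
setClass("RgbImage",
  representation(pixels = "array", view = "character", dase = "integer",
                 scaleMmPerPx = "numeric", plantId = "character",
                 condition = "character"),
  prototype(view = "top", dase = 0L, scaleMmPerPx = NA_real_,
            plantId = "plant", condition = "Control"))

setValidity("RgbImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("image must have at least one pixel")
  px <- object@pixels
  if (any(!is.finite(px)) || min(px) < 0 || max(px) > 255)
    return("channel values must lie in [0, 255]")
  if (!(object@view %in% .VIEWS)) return("view must be 'top' or 'side'")
  if (!(object@condition %in% .CONDITIONS))
    return(sprintf("condition must be one of %s", paste(.CONDITIONS, collapse = ", ")))
  if (!is.na(object@scaleMmPerPx) && object@scaleMmPerPx <= 0)
    return("scaleMmPerPx must be positive when present")
  TRUE
})

#' Construct an RgbImage
#'
#' @param pixels H x W x 3 array of intensities in [0, 255]
#' @param view "top" or "side"
#' @param dase integer day after shoot emergence
#' @param scaleMmPerPx optional mm-per-pixel calibration (NA = pixel units)
#' @param plantId plant identifier
#' @param condition "Control", "MWD" or "SWD"
#' @return an \code{RgbImage} object
#' @examples
#' px <- array(c(0, 255, 0), c(1, 1, 3))  # one pure-green pixel
#' img <- RgbImage(px, view = "top", dase = 25L)
#' @export
RgbImage <- function(pixels, view = "top", dase = 0L, scaleMmPerPx = NA_real_,
                     plantId = "plant", condition = "Control") {
  new("RgbImage", pixels = pixels, view = view, dase = as.integer(dase),
      scaleMmPerPx = as.numeric(scaleMmPerPx), plantId = plantId,
      condition = condition)
}

#' PlantMask: boolean foreground mask of a segmented plant
#'
#' @slot mask logical H x W matrix, TRUE = plant foreground
#' @aliases PlantMask-class
#' @exportClass PlantMask
setClass("PlantMask", representation(mask = "matrix"))

setValidity("PlantMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (any(is.na(object@mask))) return("mask must not contain NA")
  TRUE
})

#' Construct a PlantMask
#' @param mask logical H x W matrix
#' @return a \code{PlantMask} object
#' @export
PlantMask <- function(mask) {
  storage.mode(mask) <- "logical"
  new("PlantMask", mask = mask)
}

#' CpmgDecay: a CPMG transverse-relaxation echo train
#'
#' Echo amplitudes S(t_k) sampled at t_k = 2 k tau for half-echo spacing
#' tau (0.2 ms in the reference acquisition), with the known or estimated
#' Gaussian noise level and the sample metadata (leaf rank, DASE,
#' condition, replicate) used for grouping.
#'
#' @slot times echo times in ms, strictly increasing and positive
#' @slot amplitudes signal amplitudes at the echo times
#' @slot noiseSigma Gaussian noise sd, or NA when unknown
#' @slot meta named list of sample metadata
#' @aliases CpmgDecay-class
#' @exportClass CpmgDecay
setClass("CpmgDecay",
  representation(times = "numeric", amplitudes = "numeric",
                 noiseSigma = "numeric", meta = "list"),
  prototype(noiseSigma = NA_real_, meta = list()))

setValidity("CpmgDecay", function(object) {
  if (length(object@times) < 2L) return("at least 2 echoes are required")
  if (length(object@times) != length(object@amplitudes))
    return("times and amplitudes must have the same length")
  if (any(object@times <= 0) || any(diff(object@times) <= 0))
    return("echo times must be positive and strictly increasing")
  if (!is.na(object@noiseSigma) && object@noiseSigma < 0)
    return("noiseSigma must be non-negative")
  TRUE
})

#' Construct a CpmgDecay
#' @param times echo times in ms (strictly increasing, positive)
#' @param amplitudes echo amplitudes
#' @param noiseSigma Gaussian noise sd (NA = estimate from decay tail)
#' @param meta named list of sample metadata (leaf_rank, dase, condition, ...)
#' @return a \code{CpmgDecay} object
#' @export
CpmgDecay <- function(times, amplitudes, noiseSigma = NA_real_, meta = list()) {
  new("CpmgDecay", times = as.numeric(times), amplitudes = as.numeric(amplitudes),
      noiseSigma = as.numeric(noiseSigma), meta = meta)
}

#' T2Distribution: a continuous T2 relaxation spectrum on a log grid
#'
#' The non-negative amplitude distribution recovered from a CPMG decay by
#' an inverse-Laplace solver, together with the fitted constant baseline
#' offset and goodness-of-fit diagnostics.
#'
#' @slot t2 T2 grid values in ms (log-spaced, strictly increasing)
#' @slot density non-negative amplitude per grid point (sums to total signal)
#' @slot offset fitted constant baseline offset
#' @slot chisqPerEcho chi-square per fitted data point
#' @slot solver "mem" or "nnls"
#' @slot details solver diagnostics (regularisation level, iterations, ...)
#' @aliases T2Distribution-class
#' @exportClass T2Distribution
setClass("T2Distribution",
  representation(t2 = "numeric", density = "numeric", offset = "numeric",
                 chisqPerEcho = "numeric", solver = "character",
                 details = "list"),
  prototype(offset = 0, chisqPerEcho = NA_real_, solver = "mem",
            details = list()))

setValidity("T2Distribution", function(object) {
  if (length(object@t2) != length(object@density))
    return("t2 grid and density must have the same length")
  if (any(object@t2 <= 0) || any(diff(object@t2) <= 0))
    return("t2 grid must be positive and strictly increasing")
  if (any(object@density < -1e-12)) return("density must be non-negative")
  if (!all(is.finite(object@density))) return("density must be finite")
  TRUE
})

#' Volume3D: a 3-D MR intensity volume with anisotropic voxels
#'
#' Axis order is (Z slice, Y, X); physical coordinates are 0-based voxel
#' indices times the voxel size, taken at voxel centres. The default voxel
#' size (1.1, 1.0, 1.0) mm matches the reference 3-D FSE acquisition.
#'
#' @slot voxels numeric Z x Y x X array of intensities
#' @slot voxelSize (dz, dy, dx) in mm, all positive
#' @slot dase integer day after shoot emergence
#' @slot plantId plant identifier
#' @slot condition watering condition
#' @aliases Volume3D-class
#' @exportClass Volume3D
setClass("Volume3D",
  representation(voxels = "array", voxelSize = "numeric", dase = "integer",
                 plantId = "character", condition = "character"),
  prototype(voxelSize = c(1.1, 1.0, 1.0), dase = 0L, plantId = "plant",
            condition = "Control"))

setValidity("Volume3D", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3-D array")
  if (length(object@voxels) < 1L) return("volume must be non-empty")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths (dz, dy, dx) in mm")
  TRUE
})

#' Construct a Volume3D
#' @param voxels Z x Y x X intensity array
#' @param voxelSize (dz, dy, dx) in mm; default (1.1, 1, 1)
#' @param dase integer day after shoot emergence
#' @param plantId plant identifier
#' @param condition watering condition
#' @return a \code{Volume3D} object
#' @export
Volume3D <- function(voxels, voxelSize = c(1.1, 1.0, 1.0), dase = 0L,
                     plantId = "plant", condition = "Control") {
  new("Volume3D", voxels = voxels, voxelSize = as.numeric(voxelSize),
      dase = as.integer(dase), plantId = plantId, condition = condition)
}

#' TuberLabelMap: integer-labelled 3-D tuber segmentation
#'
#' @slot labels integer Z x Y x X array, 0 = background, >= 1 = tuber label
#' @slot voxelSize (dz, dy, dx) in mm
#' @slot provenance "seeded" (grown from manual/auto seeds) or "blind"
#' @aliases TuberLabelMap-class
#' @exportClass TuberLabelMap
setClass("TuberLabelMap",
  representation(labels = "array", voxelSize = "numeric",
                 provenance = "character"),
  prototype(voxelSize = c(1.1, 1.0, 1.0), provenance = "seeded"))

setValidity("TuberLabelMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
  if (any(object@labels < 0)) return("labels must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths in mm")
  if (!(object@provenance %in% c("seeded", "blind")))
    return("provenance must be 'seeded' or 'blind'")
  TRUE
})

#' Construct a TuberLabelMap
#' @param labels integer Z x Y x X array (0 = background)
#' @param voxelSize (dz, dy, dx) in mm
#' @param provenance "seeded" or "blind"
#' @return a \code{TuberLabelMap} object
#' @export
TuberLabelMap <- function(labels, voxelSize = c(1.1, 1.0, 1.0),
                          provenance = "seeded") {
  storage.mode(labels) <- "integer"
  new("TuberLabelMap", labels = labels, voxelSize = as.numeric(voxelSize),
      provenance = provenance)
}
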