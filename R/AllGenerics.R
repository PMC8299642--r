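## Accessor generics and show methods. Slots are never accessed with @ by
## user code; these accessors are the supported surface.

#' @name accessors
#' @title Accessors for tuberphen S4 containers
#' @description Read raw data and metadata out of \code{RgbImage},
#'   \code{PlantMask}, \code{CpmgDecay}, \code{T2Distribution},
#'   \code{Volume3D} and \code{TuberLabelMap} objects.
#' @param x an object of one of the classes listed above
#' @return the slot content documented per accessor
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setGeneric("imageView", function(x) standardGeneric("imageView"))
#' @rdname accessors
#' @export
setGeneric("dase", function(x) standardGeneric("dase"))
#' @rdname accessors
#' @export
setGeneric("plantId", function(x) standardGeneric("plantId"))
#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("scaleMmPerPx", function(x) standardGeneric("scaleMmPerPx"))
#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))
#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname accessors
#' @export
setGeneric("t2Values", function(x) standardGeneric("t2Values"))
#' @rdname accessors
#' @export
setGeneric("t2Density", function(x) standardGeneric("t2Density"))
#' @rdname accessors
#' @export
setGeneric("baselineOffset", function(x) standardGeneric("baselineOffset"))
#' @rdname accessors
#' @export
setGeneric("fitChisq", function(x) standardGeneric("fitChisq"))
#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname accessors
setMethod("pixelData", "RgbImage", function(x) x@pixels)
#' @rdname accessors
setMethod("imageView", "RgbImage", function(x) x@view)
#' @rdname accessors
setMethod("dase", "RgbImage", function(x) x@dase)
#' @rdname accessors
setMethod("dase", "Volume3D", function(x) x@dase)
#' @rdname accessors
setMethod("plantId", "RgbImage", function(x) x@plantId)
#' @rdname accessors
setMethod("plantId", "Volume3D", function(x) x@plantId)
#' @rdname accessors
setMethod("condition", "RgbImage", function(x) x@condition)
#' @rdname accessors
setMethod("condition", "Volume3D", function(x) x@condition)
#' @rdname accessors
setMethod("scaleMmPerPx", "RgbImage", function(x) x@scaleMmPerPx)
#' @rdname accessors
setMethod("maskData", "PlantMask", function(x) x@mask)
#' @rdname accessors
setMethod("echoTimes", "CpmgDecay", function(x) x@times)
#' @rdname accessors
setMethod("amplitudes", "CpmgDecay", function(x) x@amplitudes)
#' @rdname accessors
setMethod("noiseSigma", "CpmgDecay", function(x) x@noiseSigma)
#' @rdname accessors
setMethod("sampleMeta", "CpmgDecay", function(x) x@meta)
#' @rdname accessors
setMethod("t2Values", "T2Distribution", function(x) x@t2)
#' @rdname accessors
setMethod("t2Density", "T2Distribution", function(x) x@density)
#' @rdname accessors
setMethod("baselineOffset", "T2Distribution", function(x) x@offset)
#' @rdname accessors
setMethod("fitChisq", "T2Distribution", function(x) x@chisqPerEcho)
#' @rdname accessors
setMethod("volumeData", "Volume3D", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelSize", "Volume3D", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "TuberLabelMap", function(x) x@voxelSize)
#' @rdname accessors
setMethod("labelData", "TuberLabelMap", function(x) x@labels)

setMethod("show", "RgbImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RgbImage %d x %d (%s view), plant '%s' [%s], DASE %d%s\n",
              d[1], d[2], object@view, object@plantId, object@condition,
              object@dase,
              if (is.na(object@scaleMmPerPx)) ", uncalibrated"
              else sprintf(", %.4g mm/px", object@scaleMmPerPx)))
})

setMethod("show", "PlantMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("PlantMask %d x %d, %d foreground px (%.2f%% of frame)\n",
              d[1], d[2], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "CpmgDecay", function(object) {
  cat(sprintf("CpmgDecay: %d echoes, t = [%.3g, %.4g] ms, sigma = %s\n",
              length(object@times), object@times[1],
              object@times[length(object@times)],
              if (is.na(object@noiseSigma)) "unknown"
              else format(object@noiseSigma, digits = 3)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "T2Distribution", function(object) {
  cat(sprintf(
    "T2Distribution (%s): %d-pt grid [%.3g, %.4g] ms, total area %.4g, chi2/K = %s\n",
    object@solver, length(object@t2), object@t2[1],
    object@t2[length(object@t2)], sum(object@density),
    if (is.na(object@chisqPerEcho)) "NA"
    else format(object@chisqPerEcho, digits = 3)))
})

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "Volume3D %d x %d x %d (Z,Y,X), voxel %.3g x %.3g x %.3g mm, plant '%s' [%s], DASE %d\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], object@plantId, object@condition, object@dase))
})

setMethod("show", "TuberLabelMap", function(object) {
  d <- dim(object@labels)
  labs <- setdiff(sort(unique(as.integer(object@labels))), 0L)
  cat(sprintf("TuberLabelMap %d x %d x %d (%s): %d object(s)%s\n",
              d[1], d[2], d[3], object@provenance, length(labs),
              if (length(labs)) paste0(" [", paste(labs, collapse = ","), "]")
              else ""))
})
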