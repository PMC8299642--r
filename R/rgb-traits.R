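## Shoot trait extraction from top/side view RGB images: ExG-based
## segmentation and the morphological/colour traits derived from the mask.

#' Excess Green (ExG) index map and mean
#'
#' Computes the per-pixel Excess Green index
#' \deqn{ExG = (2G - (R + B)) / (R + G + B)}
#' which intensifies the greenness of the plant for higher values, and its
#' mean over the plant mask (or the whole frame when no mask is given).
#' Pixels with R + G + B = 0 are mapped to \code{zeroValue} (default 0,
#' the background-black convention).
#'
#' @param image an \code{\link{RgbImage}} or an H x W x 3 array in [0, 255]
#' @param mask optional \code{\link{PlantMask}} (or logical matrix) of the
#'   same H x W shape; when given, \code{mean} is taken over its foreground
#' @param zeroValue value assigned where R + G + B = 0
#' @return list with \code{map} (H x W matrix of ExG values, each in
#'   [-1, 2]) and \code{mean} (mean over the mask foreground, NA for an
#'   empty mask)
#' @examples
#' px <- array(c(0, 255, 0), c(1, 1, 3))
#' exgIndex(RgbImage(px))$mean  # 2: pure green
#' @export
exgIndex <- function(image, mask = NULL, zeroValue = 0) {
  px <- if (is(image, "RgbImage")) pixelData(image) else image
  stopIfNot(length(dim(px)) == 3L && dim(px)[3] == 3L,
            "image must be an H x W x 3 array")
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  s <- r + g + b
  map <- (2 * g - (r + b)) / s
  map[s == 0] <- zeroValue
  m <- NULL
  if (!is.null(mask)) {
    m <- if (is(mask, "PlantMask")) maskData(mask) else mask
    stopIfNot(identical(dim(m), dim(map)),
              "mask shape (%s) does not match image shape (%s)",
              paste(dim(m), collapse = "x"), paste(dim(map), collapse = "x"))
  }
  mu <- if (is.null(m)) mean(map)
        else if (any(m)) mean(map[m]) else NA_real_
  list(map = map, mean = mu)
}

#' Segmentation settings for the reference ExG segmenter
#'
#' @param method "otsu" (threshold the ExG map by Otsu's criterion) or
#'   "fixed" (use \code{threshold} directly)
#' @param threshold fixed ExG threshold, also used when the ExG map is
#'   constant and Otsu's criterion is undefined; must lie in [-1, 2]
#' @param openSize,closeSize box structuring-element width (px) for the
#'   morphological opening-then-closing cleanup; 0 disables the step
#' @param minComponentFrac connected components smaller than this fraction
#'   of the frame area are discarded; in [0, 1)
#' @return a list of class \code{segmentationConfig}
#' @export
segmentationConfig <- function(method = c("otsu", "fixed"), threshold = 0.1,
                               openSize = 3, closeSize = 3,
                               minComponentFrac = 0.005) {
  method <- match.arg(method)
  stopIfNot(is.numeric(threshold) && threshold >= -1 && threshold <= 2,
            "threshold must lie in [-1, 2] (ExG range)")
  stopIfNot(minComponentFrac >= 0 && minComponentFrac < 1,
            "minComponentFrac must lie in [0, 1)")
  stopIfNot(openSize >= 0 && closeSize >= 0,
            "structuring element sizes must be >= 0")
  structure(list(method = method, threshold = threshold, openSize = openSize,
                 closeSize = closeSize, minComponentFrac = minComponentFrac),
            class = "segmentationConfig")
}

#' Segment plant foreground from an RGB image
#'
#' Reference segmenter standing behind a pluggable interface (see
#' \code{segmenter} in \code{\link{buildTraitSeries}}): per-pixel ExG map,
#' Otsu threshold (or a fixed threshold), morphological opening then
#' closing with a square structuring element, and retention of connected
#' components at least \code{minComponentFrac} of the frame area. The
#' result is deterministic for a fixed configuration.
#'
#' When the ExG map is constant (zero between-class variance, so Otsu's
#' criterion is undefined) the fixed \code{threshold} is used instead, so
#' a uniform grey frame yields an empty mask and a uniform green frame a
#' full-frame mask.
#'
#' @param image an \code{\link{RgbImage}}
#' @param cfg a \code{\link{segmentationConfig}}
#' @return a \code{\link{PlantMask}}
#' @export
segmentPlant <- function(image, cfg = segmentationConfig()) {
  stopIfNot(is(image, "RgbImage"), "image must be an RgbImage")
  stopIfNot(inherits(cfg, "segmentationConfig"),
            "cfg must come from segmentationConfig()")
  exg <- exgIndex(image)$map
  thr <- if (cfg$method == "fixed" || stats::sd(exg) < 1e-9) {
    cfg$threshold
  } else {
    # Otsu expects values in [0, 1]; map ExG's [-1, 2] range onto it.
    EBImage::otsu((exg + 1) / 3, range = c(0, 1)) * 3 - 1
  }
  m <- exg > thr
  if (any(m) && cfg$openSize >= 2) {
    m <- EBImage::opening(m + 0, EBImage::makeBrush(cfg$openSize, "box")) > 0.5
  }
  if (any(m) && cfg$closeSize >= 2) {
    m <- EBImage::closing(m + 0, EBImage::makeBrush(cfg$closeSize, "box")) > 0.5
  }
  if (any(m) && cfg$minComponentFrac > 0) {
    lab <- EBImage::bwlabel(m + 0)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= cfg$minComponentFrac * length(m))
    m <- array(lab %in% keep, dim(m))
  }
  PlantMask(m)
}

.maskMatrix <- function(mask, requireForeground = FALSE) {
  m <- if (is(mask, "PlantMask")) maskData(mask) else mask
  stopIfNot(is.matrix(m) && is.logical(m), "mask must be a logical matrix")
  if (requireForeground)
    stopIfNot(any(m), "mask has no foreground pixels")
  m
}

.areaScale <- function(scaleMmPerPx) {
  if (is.na(scaleMmPerPx)) list(f = 1, units = "px^2")
  else list(f = scaleMmPerPx^2, units = "mm^2")
}

#' Projected (silhouette) area of a plant mask
#'
#' Foreground pixel count times the squared pixel pitch (px^2 when no
#' calibration is given).
#'
#' @param mask a \code{\link{PlantMask}} or logical matrix
#' @param scaleMmPerPx optional mm-per-pixel calibration
#' @return area (numeric) with a \code{units} attribute ("px^2" or "mm^2")
#' @export
projectedArea <- function(mask, scaleMmPerPx = NA_real_) {
  m <- .maskMatrix(mask)
  sc <- .areaScale(scaleMmPerPx)
  structure(sum(m) * sc$f, units = sc$units)
}

#' Convex hull area of a plant mask
#'
#' Pixels are treated as unit squares: the hull is taken over the four
#' corner points of every foreground pixel, so a single pixel has hull
#' area 1 px^2 and the hull area always contains the projected area.
#'
#' @inheritParams projectedArea
#' @return hull area with a \code{units} attribute
#' @export
convexHullArea <- function(mask, scaleMmPerPx = NA_real_) {
  m <- .maskMatrix(mask, requireForeground = TRUE)
  idx <- which(m, arr.ind = TRUE)
  # 0-based corner coordinates of each foreground pixel's unit square
  r <- idx[, 1]; c <- idx[, 2]
  pts <- cbind(c(r - 1, r, r - 1, r), c(c - 1, c - 1, c, c))
  hull <- grDevices::chull(pts)
  x <- pts[hull, 1]; y <- pts[hull, 2]
  n <- length(hull)
  area <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  sc <- .areaScale(scaleMmPerPx)
  structure(area * sc$f, units = sc$units)
}

#' Height and width of a side-view plant mask
#'
#' Vertical and horizontal extents of the foreground bounding box,
#' inclusive of end pixels (a single pixel has extent 1 x 1).
#'
#' @inheritParams projectedArea
#' @return named numeric \code{c(height, width)} with a \code{units}
#'   attribute ("px" or "mm")
#' @export
boundingExtent <- function(mask, scaleMmPerPx = NA_real_) {
  m <- .maskMatrix(mask, requireForeground = TRUE)
  idx <- which(m, arr.ind = TRUE)
  f <- if (is.na(scaleMmPerPx)) 1 else scaleMmPerPx
  structure(c(height = diff(range(idx[, 1])) + 1,
              width = diff(range(idx[, 2])) + 1) * f,
            units = if (is.na(scaleMmPerPx)) "px" else "mm")
}

#' Build a DASE-indexed trait series from a set of plant images
#'
#' Segments every image and computes the full trait record (projected
#' area, convex hull area, side-view height/width, mean ExG), returning
#' one row per image sorted by plant, view and DASE. Duplicate
#' (plant, view, DASE) combinations are an error.
#'
#' @param images list of \code{\link{RgbImage}} objects
#' @param cfg a \code{\link{segmentationConfig}} passed to the segmenter
#' @param segmenter segmentation function \code{function(image, cfg)}
#'   returning a \code{\link{PlantMask}}; defaults to
#'   \code{\link{segmentPlant}} and may be replaced by e.g. a
#'   machine-learning segmenter
#' @param exgOverMask if TRUE (default) the mean ExG is computed over the
#'   segmented plant pixels; if FALSE over the whole frame
#' @return data.frame with columns plant_id, condition, view, dase,
#'   projected_area, hull_area, height, width, exg_mean, units. Height and
#'   width are NA for top views; hull_area, height, width and exg_mean are
#'   NA when the mask is empty.
#' @export
buildTraitSeries <- function(images, cfg = segmentationConfig(),
                             segmenter = segmentPlant, exgOverMask = TRUE) {
  stopIfNot(length(images) >= 1, "at least one image is required")
  stopIfNot(all(vapply(images, is, TRUE, "RgbImage")),
            "images must be a list of RgbImage objects")
  key <- vapply(images, function(im)
    paste(plantId(im), imageView(im), dase(im), sep = "\r"), "")
  stopIfNot(!anyDuplicated(key),
            "duplicate (plant, view, dase) combination: %s",
            gsub("\r", "/", key[duplicated(key)][1]))
  rows <- lapply(images, function(im) {
    msk <- segmenter(im, cfg)
    m <- maskData(msk)
    sc <- scaleMmPerPx(im)
    pa <- projectedArea(msk, sc)
    units <- attr(pa, "units")
    empty <- !any(m)
    ha <- if (empty) NA_real_ else as.numeric(convexHullArea(msk, sc))
    hw <- if (!empty && imageView(im) == "side") boundingExtent(msk, sc)
          else c(height = NA_real_, width = NA_real_)
    ex <- if (exgOverMask) exgIndex(im, msk)$mean else exgIndex(im)$mean
    data.frame(plant_id = plantId(im), condition = condition(im),
               view = imageView(im), dase = dase(im),
               projected_area = as.numeric(pa), hull_area = ha,
               height = as.numeric(hw["height"]),
               width = as.numeric(hw["width"]),
               exg_mean = ex, units = units, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$plant_id, out$view, out$dase), , drop = FALSE]
}

#' Read an 8-bit RGB image file into an RgbImage
#'
#' Supports PNG and TIFF. Pixel values are rescaled to [0, 255]; an alpha
#' channel, if present, is dropped; greyscale images are replicated across
#' the three channels.
#'
#' @param path PNG or TIFF file
#' @inheritParams RgbImage
#' @return an \code{\link{RgbImage}}
#' @export
readRgbImage <- function(path, view = "top", dase = 0L,
                         scaleMmPerPx = NA_real_, plantId = "plant",
                         condition = "Control") {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  RgbImage(round(px * 255), view = view, dase = dase,
           scaleMmPerPx = scaleMmPerPx, plantId = plantId,
           condition = condition)
}
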