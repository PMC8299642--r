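## Reading and writing 3-D MR volumes and label maps. Internal axis order
## is (Z slice, Y, X); NIfTI files store (X, Y, Z) and are permuted on the
## way in and out.

.readVolumeArray <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    list(arr = aperm(as.array(img), c(3, 2, 1)),
         voxelSize = if (length(pd) >= 3) rev(pd[1:3]) else NULL)
  } else if (ext %in% c("tif", "tiff")) {
    # native read: float TIFFs come back as stored, integer TIFFs are
    # normalised to [0, 1] (region growing is scale-invariant)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    list(arr = arr, voxelSize = NULL)   # TIFF carries no voxel size
  } else stop("unsupported volume format: ", ext)
}

#' Load a 3-D MR volume
#'
#' Reads a NIfTI file or a multi-page TIFF stack into a
#' \code{\link{Volume3D}} with axis order normalised to (Z, Y, X). The
#' voxel size is taken from the NIfTI header when available; an explicit
#' \code{voxelSize} argument always wins (with a warning when it
#' contradicts the header). TIFF stacks carry no spacing, so the argument
#' is required for them.
#'
#' @param path .nii, .nii.gz, .tif or .tiff file
#' @param voxelSize optional (dz, dy, dx) in mm
#' @param dase,plantId,condition acquisition metadata
#' @return a \code{\link{Volume3D}}
#' @export
loadVolume <- function(path, voxelSize = NULL, dase = 0L, plantId = "plant",
                       condition = "Control") {
  rd <- .readVolumeArray(path)
  vs <- rd$voxelSize
  if (!is.null(voxelSize)) {
    if (!is.null(vs) && any(abs(vs - voxelSize) > 1e-6))
      warning(sprintf(
        "voxelSize argument (%s) overrides header spacing (%s)",
        paste(voxelSize, collapse = "x"), paste(signif(vs, 4), collapse = "x")))
    vs <- voxelSize
  }
  if (is.null(vs))
    stop("voxel size not present in the file header; supply voxelSize=")
  Volume3D(rd$arr, voxelSize = vs, dase = dase, plantId = plantId,
           condition = condition)
}

#' Save a label map or volume as NIfTI
#'
#' Writes the (Z, Y, X) array back in NIfTI (X, Y, Z) order with the voxel
#' size in the header. Integer label values round-trip losslessly.
#'
#' @param x a \code{\link{TuberLabelMap}} or \code{\link{Volume3D}}
#' @param path output .nii or .nii.gz file
#' @return \code{path}, invisibly
#' @export
saveLabelmap <- function(x, path) {
  if (is(x, "TuberLabelMap")) {
    arr <- labelData(x); vs <- voxelSize(x)
  } else if (is(x, "Volume3D")) {
    arr <- volumeData(x); vs <- voxelSize(x)
  } else stop("x must be a TuberLabelMap or Volume3D")
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(vs)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a label map from NIfTI
#'
#' @param path .nii or .nii.gz file written by \code{\link{saveLabelmap}}
#'   (or any integer-valued NIfTI)
#' @param voxelSize optional (dz, dy, dx) override in mm
#' @param provenance "seeded" or "blind"
#' @return a \code{\link{TuberLabelMap}}
#' @export
loadLabelmap <- function(path, voxelSize = NULL, provenance = "seeded") {
  rd <- .readVolumeArray(path)
  vs <- if (!is.null(voxelSize)) voxelSize else rd$voxelSize
  if (is.null(vs)) stop("voxel size unavailable; supply voxelSize=")
  TuberLabelMap(round(rd$arr), voxelSize = vs, provenance = provenance)
}

#' Build a seed label array from a voxel table
#'
#' Converts a CSV-style table of seed voxels (tuber_id, z, y, x with
#' 0-based voxel indices) into a label array matching a volume's shape.
#'
#' @param table data.frame with columns tuber_id, z, y, x (0-based)
#' @param dim volume dimensions (Z, Y, X)
#' @return integer array of seed labels (0 = background)
#' @export
seedsFromTable <- function(table, dim) {
  stopIfNot(all(c("tuber_id", "z", "y", "x") %in% names(table)),
            "table needs columns tuber_id, z, y, x")
  z <- table$z + 1L; y <- table$y + 1L; x <- table$x + 1L
  stopIfNot(all(z >= 1 & z <= dim[1] & y >= 1 & y <= dim[2] &
                x >= 1 & x <= dim[3]),
            "seed voxels outside the volume bounds")
  seeds <- array(0L, dim)
  seeds[cbind(z, y, x)] <- as.integer(table$tuber_id)
  seeds
}
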