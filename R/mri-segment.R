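## Seeded statistical region growing, 3-D connected-component counting and
## per-tuber measurement.

# Neighbourhood offsets for 6- or 26-connectivity.
connOffsets <- function(connectivity = 26) {
  stopIfNot(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  o <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  if (connectivity == 6) o <- o[rowSums(abs(o)) == 1, , drop = FALSE]
  o
}

# Breadth-first flood fill over an eligibility array, starting from linear
# indices `start`. Work per sweep is proportional to the frontier size, so
# filling costs O(object voxels x connectivity) regardless of volume size.
# Returns a logical vector over the flattened array.
floodFill3d <- function(elig, start, connectivity = 26) {
  d <- dim(elig)
  offs <- connOffsets(connectivity)
  visited <- logical(length(elig))
  start <- start[start >= 1 & start <= length(elig)]
  if (!length(start)) return(visited)
  visited[start] <- TRUE
  idx <- as.integer(start)
  z <- ((idx - 1L) %% d[1]) + 1L
  y <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  dd <- d[1] * d[2]
  while (length(idx)) {
    m <- length(idx); K <- nrow(offs)
    cz <- rep(z, K) + rep.int(offs[, 1], rep.int(m, K))
    cy <- rep(y, K) + rep.int(offs[, 2], rep.int(m, K))
    cx <- rep(x, K) + rep.int(offs[, 3], rep.int(m, K))
    ok <- cz >= 1L & cz <= d[1] & cy >= 1L & cy <= d[2] &
          cx >= 1L & cx <= d[3]
    cz <- cz[ok]; cy <- cy[ok]; cx <- cx[ok]
    lin <- cz + (cy - 1L) * d[1] + (cx - 1L) * dd
    keep <- elig[lin] & !visited[lin]
    lin <- lin[keep]; cz <- cz[keep]; cy <- cy[keep]; cx <- cx[keep]
    if (length(lin)) {
      dup <- duplicated(lin)
      lin <- lin[!dup]; cz <- cz[!dup]; cy <- cy[!dup]; cx <- cx[!dup]
      visited[lin] <- TRUE
    }
    idx <- lin; z <- cz; y <- cy; x <- cx
  }
  visited
}

#' Count and size 3-D connected objects
#'
#' For a binary mask, labels connected components under the requested
#' connectivity (26 by default, the 3-D box neighbourhood) and tallies
#' their voxel counts. For an existing label map, tallies voxels per
#' label without relabelling.
#'
#' @param x logical/0-1 3-D array, or a \code{\link{TuberLabelMap}}
#' @param connectivity 6 or 26
#' @return list with \code{count} (number of objects), \code{sizes}
#'   (named voxel counts per label) and \code{labels} (integer label
#'   array)
#' @export
labelAndCount <- function(x, connectivity = 26) {
  if (is(x, "TuberLabelMap")) {
    lab <- labelData(x)
    labs <- setdiff(sort(unique(as.integer(lab))), 0L)
    sizes <- vapply(labs, function(l) sum(lab == l), 0L)
    return(list(count = length(labs),
                sizes = stats::setNames(sizes, labs), labels = lab))
  }
  stopIfNot(length(dim(x)) == 3L, "x must be a 3-D array or TuberLabelMap")
  fg <- x > 0
  labels <- integer(length(fg))
  nextLab <- 0L
  remaining <- fg
  repeat {
    s <- which.max(remaining)          # first TRUE, 0-cost scan in C
    if (!remaining[s]) break
    nextLab <- nextLab + 1L
    comp <- floodFill3d(fg, s, connectivity)
    labels[comp] <- nextLab
    remaining <- remaining & !comp
  }
  labels <- array(labels, dim(fg))
  sizes <- if (nextLab > 0) tabulate(labels[labels > 0], nextLab) else integer(0)
  list(count = nextLab,
       sizes = stats::setNames(sizes, seq_len(nextLab)), labels = labels)
}

#' Grow tuber seeds into a full segmentation
#'
#' Statistical region growing standing in for a level-set seed expansion:
#' each seed's intensity mean and sd define an acceptance band
#' \eqn{\mu \pm k\sigma}, and the seed grows to every voxel connected to
#' it (26-connectivity by default) whose intensity lies in the band --
#' i.e. the connected component of the band's support that contains the
#' seed. A voxel eligible for several labels goes to the label with the
#' smaller seed z-score |I - mu| / sigma, ties to the lower label id. An
#' optional smoothing pass drops grown voxels with fewer than
#' \code{minNeighbors} same-label neighbours. Deterministic for fixed
#' settings.
#'
#' A seed whose band matches nothing beyond the seed itself keeps only its
#' seed voxels, with a warning. On a uniform region the band degenerates
#' to (near) exact matching and the growth covers the whole connected
#' uniform region.
#'
#' @param volume a \code{\link{Volume3D}}
#' @param seeds integer label array of seed voxels (same shape), a
#'   \code{\link{TuberLabelMap}}, or a data.frame for
#'   \code{\link{seedsFromTable}}
#' @param k acceptance half-width in seed sds (default 2.5)
#' @param connectivity 6 or 26
#' @param minNeighbors smoothing threshold (0 disables, the default)
#' @return a \code{\link{TuberLabelMap}} (provenance "seeded")
#' @export
regionGrow <- function(volume, seeds, k = 2.5, connectivity = 26,
                       minNeighbors = 0) {
  stopIfNot(is(volume, "Volume3D"), "volume must be a Volume3D")
  stopIfNot(k > 0, "k must be positive")
  v <- volumeData(volume)
  if (is.data.frame(seeds)) seeds <- seedsFromTable(seeds, dim(v))
  if (is(seeds, "TuberLabelMap")) seeds <- labelData(seeds)
  stopIfNot(identical(dim(seeds), dim(v)),
            "seeds must match the volume shape")
  labs <- setdiff(sort(unique(as.integer(seeds))), 0L)
  stopIfNot(length(labs) >= 1, "SeedSet is empty")
  out <- integer(length(v))
  zbest <- rep(Inf, length(v))
  for (l in labs) {
    sIdx <- which(seeds == l)
    mu <- mean(v[sIdx])
    sdv <- stats::sd(v[sIdx])
    if (!is.finite(sdv) || sdv < 1e-8 * max(abs(mu), 1))
      sdv <- 1e-8 * max(abs(mu), 1)   # uniform seed: (near) exact matching
    elig <- array(abs(v - mu) <= k * sdv, dim(v))
    elig[sIdx] <- TRUE                # seeds always belong to their label
    grown <- which(floodFill3d(elig, sIdx, connectivity))
    if (length(grown) <= length(sIdx))
      warning(sprintf(
        "seed %d matched no voxels beyond itself (background seed?)", l))
    z <- abs(v[grown] - mu) / sdv
    win <- z < zbest[grown]           # earlier (lower) label keeps ties
    out[grown[win]] <- l
    zbest[grown[win]] <- z[win]
  }
  out <- array(out, dim(v))
  if (minNeighbors > 0) {
    offs <- connOffsets(connectivity)
    same <- array(0L, dim(v))
    for (i in seq_len(nrow(offs))) {
      sh <- shiftArray(out, offs[i, 1], offs[i, 2], offs[i, 3])
      same <- same + (sh == out & out > 0L)
    }
    out[out > 0L & same < minNeighbors] <- 0L
  }
  TuberLabelMap(out, voxelSize = voxelSize(volume), provenance = "seeded")
}

# Shift a 3-D array by (dz, dy, dx), padding with `fill`.
shiftArray <- function(a, dz, dy, dx, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(max(1, 1 - dz):min(d[1], d[1] - dz),
              max(1, 1 - dy):min(d[2], d[2] - dy),
              max(1, 1 - dx):min(d[3], d[3] - dx))
  out[src[[1]] + dz, src[[2]] + dy, src[[3]] + dx] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Measure tubers in a label map
#'
#' Volume is voxel count times the voxel volume (1.1 mm^3 at the default
#' 1 x 1 x 1.1 mm spacing), reported in cm^3; the equivalent-sphere
#' diameter is \eqn{(6V/\pi)^{1/3}} with V in mm^3; centroids are in mm
#' (0-based voxel index times voxel size, at voxel centres).
#'
#' @param labelmap a \code{\link{TuberLabelMap}}
#' @param dase measurement day stored in the output
#' @param excludeLabels labels to drop (e.g. the mother tuber's seed
#'   label)
#' @return data.frame with columns tuber_id, dase, voxel_count,
#'   volume_cm3, eq_diameter_mm, cz, cy, cx
#' @export
measureTubers <- function(labelmap, dase = NA_integer_,
                          excludeLabels = integer(0)) {
  stopIfNot(is(labelmap, "TuberLabelMap"), "labelmap must be a TuberLabelMap")
  lab <- labelData(labelmap)
  vs <- voxelSize(labelmap)
  vvox <- prod(vs)                      # mm^3 per voxel
  labs <- setdiff(setdiff(sort(unique(as.integer(lab))), 0L),
                  as.integer(excludeLabels))
  rows <- lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    nv <- nrow(idx)
    vmm3 <- nv * vvox
    data.frame(tuber_id = l, dase = as.integer(dase), voxel_count = nv,
               volume_cm3 = vmm3 / 1000,
               eq_diameter_mm = (6 * vmm3 / pi)^(1 / 3),
               cz = mean(idx[, 1] - 1) * vs[1],
               cy = mean(idx[, 2] - 1) * vs[2],
               cx = mean(idx[, 3] - 1) * vs[3])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tuber_id = integer(0), dase = integer(0),
                      voxel_count = integer(0), volume_cm3 = numeric(0),
                      eq_diameter_mm = numeric(0), cz = numeric(0),
                      cy = numeric(0), cx = numeric(0))
  out
}
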