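## Seeded synthetic MRI tuber scenes: non-overlapping ellipsoidal tubers
## on a well-separated lattice, growing along logistic volume curves over
## the imaging sessions, plus a shrinking mother tuber that is depleted by
## the final session. Every session comes with its ground-truth label map
## and auto-generated seeds.

#' Describe a synthetic MRI tuber scene
#'
#' Tuber centres are fixed across sessions (pots keep a marked position
#' in the scanner); per-tuber volumes follow
#' \eqn{V(t) = V_{max} / (1 + e^{-k (t - t_0)})}. Contrast is
#' parameterised as \code{snr} = (object - background) / noise sd.
#' Construction fails if any two ellipsoids could overlap at maximal
#' size.
#'
#' @param seed integer seed; the scene is a pure function of it
#' @param nTubers number of daughter tubers (1..6 on the default lattice)
#' @param dims volume dimensions (Z, Y, X) in voxels
#' @param voxelSize (dz, dy, dx) in mm
#' @param dase imaging session days (strictly increasing)
#' @param vmaxRange range of logistic asymptotic volumes (cm^3)
#' @param growthRate logistic rate k per day
#' @param t0Range range of logistic midpoints (DASE)
#' @param intensityBg,intensityObj mean background / tuber intensity
#' @param snr (intensityObj - intensityBg) / noise sd
#' @param mother include a shrinking mother tuber (depleted at the final
#'   session)
#' @param motherVolume mother tuber volume at the first session (cm^3)
#' @return list of class \code{mriScene} including per-tuber ground-truth
#'   parameters
#' @export
mriScene <- function(seed = 1, nTubers = 6, dims = c(56, 96, 96),
                     voxelSize = c(1.1, 1, 1), dase = c(25, 32, 39, 73),
                     vmaxRange = c(0.8, 6), growthRate = 0.35,
                     t0Range = c(18, 28), intensityBg = 50,
                     intensityObj = 200, snr = 10, mother = TRUE,
                     motherVolume = 4) {
  stopIfNot(nTubers >= 1 && nTubers <= 6,
            "the default lattice supports 1 to 6 tubers")
  stopIfNot(all(diff(dase) > 0) && length(dase) >= 2,
            "dase must be strictly increasing with >= 2 sessions")
  stopIfNot(snr > 0, "snr must be positive")
  extent <- dims * voxelSize                      # (Z, Y, X) mm
  scene <- withLocalSeed(seed, {
    lattice <- expand.grid(y = c(20, extent[2] - 20),
                           x = c(16, extent[3] / 2, extent[3] - 16))
    slots <- sample(nrow(lattice))[seq_len(nTubers)]
    tubers <- data.frame(
      label = seq_len(nTubers),
      cz = extent[1] / 2 + stats::runif(nTubers, -6, 6),
      cy = lattice$y[slots] + stats::runif(nTubers, -2, 2),
      cx = lattice$x[slots] + stats::runif(nTubers, -2, 2),
      vmax = stats::runif(nTubers, vmaxRange[1], vmaxRange[2]),
      t0 = stats::runif(nTubers, t0Range[1], t0Range[2]),
      az = exp(stats::runif(nTubers, -0.08, 0.08)),
      ay = exp(stats::runif(nTubers, -0.08, 0.08)),
      ax = exp(stats::runif(nTubers, -0.08, 0.08)))
    norm <- (tubers$az * tubers$ay * tubers$ax)^(1 / 3)
    tubers$az <- tubers$az / norm; tubers$ay <- tubers$ay / norm
    tubers$ax <- tubers$ax / norm
    tubers
  })
  motherLabel <- if (mother) nTubers + 1L else NA_integer_
  if (mother)
    scene <- rbind(scene, data.frame(
      label = motherLabel, cz = extent[1] / 2, cy = extent[2] / 2,
      cx = extent[3] / 2, vmax = motherVolume, t0 = NA, az = 1, ay = 1,
      ax = 1))
  # overlap check at maximal size (vmax for daughters, first-session
  # volume for the mother)
  rmax <- (3 * scene$vmax * 1000 / (4 * pi))^(1 / 3) *
    pmax(scene$az, scene$ay, scene$ax)
  ctr <- as.matrix(scene[, c("cz", "cy", "cx")])
  for (i in seq_len(nrow(scene) - 1)) for (j in (i + 1):nrow(scene)) {
    if (sqrt(sum((ctr[i, ] - ctr[j, ])^2)) < rmax[i] + rmax[j] + 2)
      stop(sprintf("tubers %d and %d could overlap at maximal size",
                   scene$label[i], scene$label[j]))
  }
  structure(list(seed = as.integer(seed), nTubers = nTubers, dims = dims,
                 voxelSize = voxelSize, dase = dase,
                 growthRate = growthRate, intensityBg = intensityBg,
                 intensityObj = intensityObj, snr = snr,
                 motherLabel = motherLabel, tubers = scene),
            class = "mriScene")
}

# Ground-truth volume (cm^3) of every object at day d.
.sceneVolumes <- function(scene, d) {
  tb <- scene$tubers
  v <- ifelse(is.na(tb$t0),
              tb$vmax * pmax(0, 1 - (d - scene$dase[1]) /
                                (max(scene$dase) - scene$dase[1]))^1.5,
              tb$vmax / (1 + exp(-scene$growthRate * (d - tb$t0))))
  stats::setNames(v, tb$label)
}

# Voxelise one ellipsoid into the label array (modified in place).
.paintEllipsoid <- function(labels, scene, row, volumeCm3) {
  if (volumeCm3 <= 0) return(labels)
  d <- scene$dims; vs <- scene$voxelSize
  reff <- (3 * volumeCm3 * 1000 / (4 * pi))^(1 / 3)
  rz <- reff * row$az; ry <- reff * row$ay; rx <- reff * row$ax
  qz <- (((seq_len(d[1]) - 1) * vs[1] - row$cz) / rz)^2
  qy <- (((seq_len(d[2]) - 1) * vs[2] - row$cy) / ry)^2
  qx <- (((seq_len(d[3]) - 1) * vs[3] - row$cx) / rx)^2
  inside <- outer(outer(qz, qy, "+"), qx, "+") <= 1
  labels[inside] <- as.integer(row$label)
  labels
}

# Auto-seeds: for each label take 1-2 central slices of its ground-truth
# mask and erode them in-plane, mimicking a manual contour drawn safely
# inside the tuber on a slice or two.
.autoSeeds <- function(truth) {
  d <- dim(truth)
  seeds <- array(0L, d)
  for (l in setdiff(sort(unique(as.integer(truth))), 0L)) {
    zs <- which(apply(truth == l, 1, any))
    mid <- zs[ceiling(length(zs) / 2)]
    planes <- unique(c(mid, if ((mid + 1) %in% zs) mid + 1))
    for (z in planes) {
      sl <- truth[z, , ] == l
      er <- sl
      for (pass in 1:2) {
        nb <- er & rbind(FALSE, er[-nrow(er), ]) &
          rbind(er[-1, ], FALSE) & cbind(FALSE, er[, -ncol(er)]) &
          cbind(er[, -1], FALSE)
        if (any(nb)) er <- nb
      }
      plane <- seeds[z, , ]
      plane[er] <- l
      seeds[z, , ] <- plane
    }
    if (!any(seeds == l)) {           # tiny tuber: fall back to one voxel
      idx <- which(truth == l, arr.ind = TRUE)
      ctrIdx <- idx[which.min(rowSums(
        sweep(idx, 2, colMeans(idx))^2)), , drop = FALSE]
      seeds[ctrIdx] <- l
    }
  }
  seeds
}

#' Generate a synthetic longitudinal MRI tuber scene
#'
#' Renders each session as tuber ellipsoids at \code{intensityObj} over a
#' \code{intensityBg} background plus Gaussian noise, with the
#' ground-truth label map and auto-generated seed labels. Deterministic
#' per scene seed.
#'
#' @param scene an \code{\link{mriScene}}
#' @param plantId,condition metadata stamped on the volumes
#' @return list with \code{sessions} (per day: \code{dase}, \code{volume}
#'   (\code{\link{Volume3D}}), \code{truth} (\code{\link{TuberLabelMap}}),
#'   \code{seeds} (integer label array)), \code{truthVolumes} (data.frame
#'   label, dase, volume_cm3 analytic, voxel_volume_cm3 as voxelised),
#'   \code{tubers} (ground-truth parameters) and \code{motherLabel}
#' @export
makeMriScene <- function(scene, plantId = "sim-plant",
                         condition = "Control") {
  stopIfNot(inherits(scene, "mriScene"), "scene must come from mriScene()")
  sigma <- (scene$intensityObj - scene$intensityBg) / scene$snr
  truthRows <- list()
  sessions <- lapply(seq_along(scene$dase), function(si) {
    d <- scene$dase[si]
    vols <- .sceneVolumes(scene, d)
    labels <- array(0L, scene$dims)
    for (i in seq_len(nrow(scene$tubers)))
      labels <- .paintEllipsoid(labels, scene, scene$tubers[i, ],
                                vols[as.character(scene$tubers$label[i])])
    intens <- array(scene$intensityBg, scene$dims)
    intens[labels > 0] <- scene$intensityObj
    noise <- withLocalSeed(subSeed(scene$seed, si),
                           stats::rnorm(length(intens), sd = sigma))
    vol <- Volume3D(intens + array(noise, scene$dims),
                    voxelSize = scene$voxelSize, dase = as.integer(d),
                    plantId = plantId, condition = condition)
    truthRows[[si]] <<- data.frame(
      label = scene$tubers$label, dase = d, volume_cm3 = unname(vols),
      voxel_volume_cm3 = vapply(scene$tubers$label, function(l)
        sum(labels == l) * prod(scene$voxelSize) / 1000, 0))
    list(dase = d, volume = vol,
         truth = TuberLabelMap(labels, voxelSize = scene$voxelSize),
         seeds = .autoSeeds(labels))
  })
  list(sessions = sessions, truthVolumes = do.call(rbind, truthRows),
       tubers = scene$tubers, motherLabel = scene$motherLabel)
}
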