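## Peak detection on T2 distributions, vacuolar component assignment and
## split/merge tracking across leaf development.

#' Detect peaks in a T2 distribution
#'
#' Peaks are local maxima of the density; each peak's support runs from
#' the flanking local minimum (assigned to the peak on its left) to the
#' next, or to the grid ends. Peak area is the summed amplitude over the
#' support, and the most probable T2 (the mode) is the grid value at the
#' maximum. Local maxima whose modes lie closer than \code{mergeRatio}
#' are merged into one peak before filtering: structure below the
#' intrinsic resolution limit of inverse-Laplace inversion (components
#' within about a factor 1.5 in T2 are not separable) is an artefact of
#' the solver, typically sparse NNLS solutions splitting one component
#' into adjacent spikes. Peaks with an area fraction below
#' \code{minAreaFraction} are then discarded, so fractions over reported
#' peaks sum to at most 1.
#'
#' @param dist a \code{\link{T2Distribution}}
#' @param minAreaFraction minimum fraction of total area for a peak to be
#'   reported (default 0.01)
#' @param mergeRatio adjacent maxima with a mode ratio below this are
#'   treated as one peak (default 1.5, the resolution limit; 1 disables)
#' @return data.frame sorted by ascending \code{t2_mode} with columns
#'   t2_mode, area, area_fraction, left, right (grid indices), left_t2,
#'   right_t2; zero rows when the distribution is empty
#' @export
findPeaks <- function(dist, minAreaFraction = 0.01, mergeRatio = 1.5) {
  stopIfNot(is(dist, "T2Distribution"), "dist must be a T2Distribution")
  f <- t2Density(dist)
  t2 <- t2Values(dist)
  n <- length(f)
  total <- sum(f)
  empty <- data.frame(t2_mode = numeric(0), area = numeric(0),
                      area_fraction = numeric(0), left = integer(0),
                      right = integer(0), left_t2 = numeric(0),
                      right_t2 = numeric(0))
  if (total <= 0) return(empty)
  fp <- c(-Inf, f, -Inf)
  maxima <- which(fp[2:(n + 1)] > fp[1:n] & fp[2:(n + 1)] >= fp[3:(n + 2)])
  if (!length(maxima)) return(empty)
  # support boundaries: the minimum between consecutive maxima closes the
  # left peak; the right peak starts just after it
  bounds <- matrix(0L, length(maxima), 2)
  left <- 1L
  for (i in seq_along(maxima)) {
    right <- if (i < length(maxima)) {
      between <- maxima[i]:maxima[i + 1]
      between[which.min(f[between])]
    } else n
    bounds[i, ] <- c(left, right)
    left <- right + 1L
  }
  # merge maxima closer than the resolution limit (sub-resolution
  # structure cannot reflect separate relaxation components)
  if (mergeRatio > 1 && length(maxima) > 1) {
    repeat {
      ratios <- t2[maxima[-1]] / t2[maxima[-length(maxima)]]
      j <- which(ratios < mergeRatio)
      if (!length(j)) break
      j <- j[1]
      merged <- bounds[j, 1]:bounds[j + 1, 2]
      keepMode <- merged[which.max(f[merged])]
      maxima <- c(maxima[seq_len(j - 1)], keepMode,
                  maxima[-seq_len(j + 1)])
      bounds <- rbind(bounds[seq_len(j - 1), , drop = FALSE],
                      c(bounds[j, 1], bounds[j + 1, 2]),
                      bounds[-seq_len(j + 1), , drop = FALSE])
    }
  }
  area <- vapply(seq_along(maxima),
                 function(i) sum(f[bounds[i, 1]:bounds[i, 2]]), 0)
  out <- data.frame(t2_mode = t2[maxima], area = area,
                    area_fraction = area / total,
                    left = bounds[, 1], right = bounds[, 2],
                    left_t2 = t2[bounds[, 1]], right_t2 = t2[bounds[, 2]])
  out <- out[out$area_fraction >= minAreaFraction, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$t2_mode), , drop = FALSE]
}

#' Assign vacuolar labels to detected T2 peaks
#'
#' Operationalises the convention that the longest-T2 peak(s) with high
#' relative intensity carry the vacuolar water signal. Candidate vacuolar
#' peaks are those with a mode above \code{t2Floor} and an area fraction
#' of at least \code{minFraction}. If two or more candidates qualify, the
#' two with the longest T2 are labelled vs (shorter: spongy-mesophyll
#' vacuoles) and vl (longer: palisade); if exactly one qualifies it is
#' labelled vt (all mesophyll cells, undifferentiated). When no peak
#' clears the dominance rule, the longest-T2 peak is labelled vt as a
#' fallback.
#'
#' @param peaks data.frame from \code{\link{findPeaks}} (>= 1 row)
#' @param t2Floor minimum vacuolar T2 mode in ms (default 30)
#' @param minFraction minimum area fraction for a vacuolar candidate
#'   (default 0.15)
#' @return list with \code{labels} (named numeric of modes: vt, or vs and
#'   vl with vl > vs), \code{nComponents} (1 or 2) and \code{peaks} (the
#'   labelled subset with a \code{label} column)
#' @export
assignVacuolar <- function(peaks, t2Floor = 30, minFraction = 0.15) {
  stopIfNot(is.data.frame(peaks) && nrow(peaks) >= 1,
            "at least one peak is required")
  cand <- which(peaks$t2_mode >= t2Floor & peaks$area_fraction >= minFraction)
  if (length(cand) >= 2) {
    pick <- cand[order(peaks$t2_mode[cand], decreasing = TRUE)][1:2]
    pick <- sort(pick)
    sel <- peaks[pick, , drop = FALSE]
    sel$label <- c("vs", "vl")
    labels <- c(vs = sel$t2_mode[1], vl = sel$t2_mode[2])
  } else {
    pick <- if (length(cand) == 1) cand else which.max(peaks$t2_mode)
    sel <- peaks[pick, , drop = FALSE]
    sel$label <- "vt"
    labels <- c(vt = sel$t2_mode[1])
  }
  rownames(sel) <- NULL
  list(labels = labels, nComponents = length(labels), peaks = sel)
}

#' Detect vacuolar split and merge events along a DASE trajectory
#'
#' A split is recorded at the first DASE where the vacuolar component
#' count increases (1 to 2), a merge where it decreases; multiple events
#' are allowed, capturing merge-split-merge sequences seen in senescing
#' leaves.
#'
#' @param dase strictly increasing integer vector of measurement days
#' @param nComponents vacuolar component count (1 or 2) at each DASE, or a
#'   list of \code{\link{assignVacuolar}} results
#' @return data.frame with columns event ("split"/"merge") and dase, zero
#'   rows when the count never changes
#' @examples
#' detectSplitMerge(c(32, 39, 46, 60), c(2, 1, 2, 1))
#' @export
detectSplitMerge <- function(dase, nComponents) {
  stopIfNot(length(dase) >= 2, "at least two time points are required")
  stopIfNot(all(diff(dase) > 0), "dase must be strictly increasing")
  if (is.list(nComponents))
    nComponents <- vapply(nComponents, function(a) a$nComponents, 0L)
  stopIfNot(length(nComponents) == length(dase),
            "dase and nComponents lengths differ")
  d <- diff(nComponents)
  idx <- which(d != 0)
  data.frame(event = ifelse(d[idx] > 0, "split", "merge"),
             dase = dase[idx + 1])
}

#' Average T2 parameters over homogeneous replicate groups
#'
#' Replicates are partitioned by their vacuolar component count and the
#' mode of each label (vt, or vs/vl) is averaged only within partitions,
#' so one- and two-component spectra are never mixed. The standard
#' deviation is NA for singleton partitions.
#'
#' @param assignments list of \code{\link{assignVacuolar}} results (one
#'   per replicate)
#' @param minSize partitions smaller than this are dropped from the output
#'   (default 1 = report all)
#' @return data.frame with columns n_components, label, mean_t2, sd_t2,
#'   n_replicates
#' @export
averageHomogeneous <- function(assignments, minSize = 1) {
  stopIfNot(length(assignments) >= 1, "at least one replicate is required")
  counts <- vapply(assignments, function(a) a$nComponents, 0L)
  out <- list()
  for (k in sort(unique(counts))) {
    grp <- assignments[counts == k]
    if (length(grp) < minSize) next
    labs <- names(grp[[1]]$labels)
    for (lb in labs) {
      v <- vapply(grp, function(a) unname(a$labels[lb]), 0)
      out[[length(out) + 1]] <- data.frame(
        n_components = k, label = lb, mean_t2 = mean(v),
        sd_t2 = if (length(v) >= 2) stats::sd(v) else NA_real_,
        n_replicates = length(v))
    }
  }
  do.call(rbind, out)
}

#' Run the full relaxometry pipeline on a series of decays
#'
#' Inverts each decay, detects peaks, assigns vacuolar labels and detects
#' split/merge events across the DASE axis.
#'
#' @param decays list of \code{\link{CpmgDecay}} objects, each carrying a
#'   \code{dase} entry in its metadata (or supply \code{dase})
#' @param dase optional explicit DASE vector overriding the metadata
#' @param solver "mem" or "nnls"
#' @param grid T2 grid
#' @param minAreaFraction passed to \code{\link{findPeaks}}
#' @param t2Floor,minFraction passed to \code{\link{assignVacuolar}}
#' @param ... further arguments for the chosen solver
#' @return list with \code{table} (data.frame: dase, n_components, and the
#'   vt/vs/vl modes), \code{events} (from \code{\link{detectSplitMerge}})
#'   and \code{assignments}
#' @export
analyzeT2Series <- function(decays, dase = NULL, solver = c("mem", "nnls"),
                            grid = t2Grid(), minAreaFraction = 0.01,
                            t2Floor = 30, minFraction = 0.15, ...) {
  solver <- match.arg(solver)
  if (is.null(dase))
    dase <- vapply(decays, function(d) as.numeric(sampleMeta(d)$dase), 0)
  stopIfNot(!any(is.na(dase)), "dase missing from decay metadata")
  ord <- order(dase)
  decays <- decays[ord]; dase <- dase[ord]
  assignments <- lapply(decays, function(d) {
    dist <- if (solver == "mem") invertMem(d, grid, ...)
            else invertNnls(d, grid, ...)
    pk <- findPeaks(dist, minAreaFraction)
    if (!nrow(pk)) return(NULL)
    assignVacuolar(pk, t2Floor = t2Floor, minFraction = minFraction)
  })
  keep <- !vapply(assignments, is.null, TRUE)
  asg <- assignments[keep]
  dk <- dase[keep]
  tab <- do.call(rbind, lapply(seq_along(asg), function(i) {
    lb <- asg[[i]]$labels
    data.frame(dase = dk[i], n_components = asg[[i]]$nComponents,
               vt = unname(lb["vt"]), vs = unname(lb["vs"]),
               vl = unname(lb["vl"]))
  }))
  events <- if (length(asg) >= 2) detectSplitMerge(dk, asg)
            else data.frame(event = character(0), dase = numeric(0))
  list(table = tab, events = events, assignments = asg)
}
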