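## Seeded synthetic plant-image generator: procedural green silhouettes
## (random-walk stems carrying elliptical leaflets) on a textured
## grey-brown soil background, with the silhouette area following a
## logistic growth curve and the ground-truth mask returned with every
## frame.

#' Describe a synthetic plant-image scenario
#'
#' The silhouette area A(d) follows the logistic curve
#' \eqn{A(d) = A_{max} / (1 + e^{-r (d - d_0)})} over DASE d, the sigmoid
#' shape shoot growth curves typically take. The plant shape itself is a
#' fixed (seeded) arrangement of stems and leaflets, rescaled per day to
#' hit the target area.
#'
#' @param seed integer seed; the whole scenario is a pure function of it
#' @param view "top" or "side"
#' @param width,height frame size in px
#' @param maxArea logistic asymptote A_max in px^2
#' @param rate logistic rate r per day
#' @param midpointDase logistic midpoint d_0 in DASE
#' @param nStems number of stems
#' @param plantId,condition metadata stamped on the images
#' @return list of class \code{plantImageScenario}
#' @export
plantImageScenario <- function(seed = 1, view = c("top", "side"),
                               width = 200, height = 200, maxArea = 6000,
                               rate = 0.3, midpointDase = 30, nStems = 3,
                               plantId = "sim-plant", condition = "Control") {
  view <- match.arg(view)
  stopIfNot(all(is.finite(c(width, height, maxArea, rate, midpointDase))),
            "scenario parameters must be finite")
  stopIfNot(maxArea >= 0 && width >= 16 && height >= 16,
            "frame must be at least 16 x 16 and maxArea >= 0")
  structure(list(seed = as.integer(seed), view = view, width = width,
                 height = height, maxArea = maxArea, rate = rate,
                 midpointDase = midpointDase, nStems = nStems,
                 plantId = plantId, condition = condition),
            class = "plantImageScenario")
}

# Sample the fixed plant shape (stem polylines + leaflet ellipses) in
# coordinates relative to the anchor point. Pure function of the seed.
.plantShape <- function(scenario) {
  withLocalSeed(scenario$seed, {
    discs <- list(); ellipses <- list()
    for (s in seq_len(scenario$nStems)) {
      ang <- if (scenario$view == "top") stats::runif(1, 0, 2 * pi)
             else stats::runif(1, -pi / 2 - 0.5, -pi / 2 + 0.5)
      pos <- c(0, 0)
      for (step in 1:12) {
        ang <- ang + stats::rnorm(1, sd = 0.25)
        nxt <- pos + 6 * c(sin(ang), cos(ang))
        for (f in seq(0, 1, by = 0.35))
          discs[[length(discs) + 1]] <- pos + f * (nxt - pos)
        pos <- nxt
        if (step >= 3 && stats::runif(1) < 0.6)
          ellipses[[length(ellipses) + 1]] <-
            c(pos, a = stats::runif(1, 7, 10), b = stats::runif(1, 4, 6),
              th = stats::runif(1, 0, pi))
      }
    }
    list(discs = do.call(rbind, discs), ellipses = do.call(rbind, ellipses))
  })
}

# Rasterise the shape at scale s around the anchor; returns a logical mask.
.renderShape <- function(shape, scenario, s) {
  H <- scenario$height; W <- scenario$width
  anchor <- if (scenario$view == "top") c(H / 2, W / 2) else c(H - 1, W / 2)
  R <- matrix(seq_len(H), H, W)
  C <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- matrix(FALSE, H, W)
  rs <- max(2.2, 2.8 * s)
  for (i in seq_len(nrow(shape$discs))) {
    ctr <- anchor + s * shape$discs[i, ]
    m <- m | ((R - ctr[1])^2 + (C - ctr[2])^2 <= rs^2)
  }
  for (i in seq_len(nrow(shape$ellipses))) {
    e <- shape$ellipses[i, ]
    ctr <- anchor + s * e[1:2]
    a <- max(2.2, e["a"] * s); b <- max(2.2, e["b"] * s)
    dr <- R - ctr[1]; dc <- C - ctr[2]
    u <- dr * cos(e["th"]) + dc * sin(e["th"])
    w <- -dr * sin(e["th"]) + dc * cos(e["th"])
    m <- m | ((u / a)^2 + (w / b)^2 <= 1)
  }
  m
}

#' Generate synthetic plant images with ground-truth masks
#'
#' For every requested day the fixed plant shape is rescaled so the
#' rasterised silhouette area matches the logistic target (discretisation
#' keeps it within a few percent), painted in green hues over a textured
#' grey-brown background, and returned together with its ground-truth
#' mask. Bit-identical for a given scenario.
#'
#' @param scenario a \code{\link{plantImageScenario}}
#' @param dase integer vector of acquisition days
#' @return list with one element per day: \code{image}
#'   (\code{\link{RgbImage}}), \code{mask} (\code{\link{PlantMask}},
#'   ground truth), \code{dase}, \code{targetArea} and \code{trueArea}
#'   (px^2)
#' @export
makePlantImages <- function(scenario, dase) {
  stopIfNot(inherits(scenario, "plantImageScenario"),
            "scenario must come from plantImageScenario()")
  shape <- .plantShape(scenario)
  baseArea <- sum(.renderShape(shape, scenario, 1))
  lapply(seq_along(dase), function(i) {
    d <- dase[i]
    target <- scenario$maxArea /
      (1 + exp(-scenario$rate * (d - scenario$midpointDase)))
    mask <- if (target < 4) {
      matrix(FALSE, scenario$height, scenario$width)
    } else {
      .renderShape(shape, scenario, sqrt(target / baseArea))
    }
    px <- withLocalSeed(subSeed(scenario$seed, i), {
      H <- scenario$height; W <- scenario$width
      bg <- c(115, 105, 88); fg <- c(55, 150, 60)
      arr <- array(0, c(H, W, 3))
      for (ch in 1:3) {
        plane <- bg[ch] + stats::rnorm(H * W, sd = 8)
        plane[mask] <- fg[ch] + stats::rnorm(sum(mask), sd = 12)
        arr[, , ch] <- plane
      }
      round(pmin(pmax(arr, 0), 255))
    })
    list(image = RgbImage(px, view = scenario$view, dase = as.integer(d),
                          plantId = scenario$plantId,
                          condition = scenario$condition),
         mask = PlantMask(mask), dase = d, targetArea = target,
         trueArea = sum(mask))
  })
}
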