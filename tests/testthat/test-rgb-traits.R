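test_that("ExG matches its closed form on canonical pixels", {
  px <- function(r, g, b) RgbImage(array(c(r, g, b), c(1, 1, 3)))
  expect_equal(exgIndex(px(0, 255, 0))$mean, 2)
  expect_equal(exgIndex(px(255, 0, 0))$mean, -1)
  expect_equal(exgIndex(px(80, 80, 80))$mean, 0)
  # zero-denominator pixel maps to the background convention
  expect_equal(exgIndex(px(0, 0, 0))$mean, 0)
  expect_equal(exgIndex(px(0, 0, 0), zeroValue = -1)$mean, -1)
})

test_that("ExG map stays within [-1, 2] on random images and masks", {
  set.seed(41)
  for (i in 1:20) {
    img <- RgbImage(array(sample(0:255, 30 * 30 * 3, TRUE), c(30, 30, 3)))
    e <- exgIndex(img)
    expect_true(all(e$map >= -1 - 1e-12 & e$map <= 2 + 1e-12))
    m <- matrix(runif(900) < 0.4, 30, 30)
    if (any(m)) {
      em <- exgIndex(img, PlantMask(m))
      expect_gte(em$mean, -1)
      expect_lte(em$mean, 2)
    }
  }
})

test_that("ExG rejects a mask whose shape mismatches the image", {
  img <- RgbImage(array(100, c(4, 4, 3)))
  expect_error(exgIndex(img, matrix(TRUE, 3, 3)), "shape")
})

test_that("segmentation handles uniform frames by the fixed threshold", {
  grey <- RgbImage(array(120, c(24, 24, 3)))
  expect_equal(sum(maskData(segmentPlant(grey))), 0)
  green <- RgbImage(array(rep(c(0, 255, 0), each = 24 * 24), c(24, 24, 3)))
  expect_equal(sum(maskData(segmentPlant(green))), 24 * 24)
})

test_that("segmentation recovers fixture silhouettes (median IoU >= 0.95)", {
  ious <- vapply(1:50, function(s) {
    sc <- plantImageScenario(seed = s, maxArea = 5000)
    it <- makePlantImages(sc, 40)[[1]]
    iouCoef(maskData(segmentPlant(it$image)), maskData(it$mask))
  }, 0)
  expect_gte(median(ious), 0.95)
})

test_that("invalid segmentation settings are rejected", {
  expect_error(segmentationConfig(threshold = 5), "\\[-1, 2\\]")
  expect_error(segmentationConfig(minComponentFrac = 1.5), "\\[0, 1\\)")
  expect_error(segmentPlant(RgbImage(array(0, c(2, 2, 3)) - 1)),
               "\\[0, 255\\]")
})

test_that("projected area counts pixels and applies the calibration", {
  full <- PlantMask(matrix(TRUE, 10, 10))
  expect_equal(as.numeric(projectedArea(full)), 100)
  expect_equal(attr(projectedArea(full), "units"), "px^2")
  expect_equal(as.numeric(projectedArea(full, 2)), 400)
  expect_equal(attr(projectedArea(full, 2), "units"), "mm^2")
  expect_equal(as.numeric(projectedArea(PlantMask(matrix(FALSE, 5, 5)))), 0)
})

test_that("convex hull uses the pixel-corner convention", {
  one <- matrix(FALSE, 8, 8); one[3, 5] <- TRUE
  expect_equal(as.numeric(convexHullArea(PlantMask(one))), 1)
  row3 <- matrix(FALSE, 5, 5); row3[2, 2:4] <- TRUE
  expect_equal(as.numeric(convexHullArea(PlantMask(row3))), 3)
  # two diagonal pixels: brute-force shoelace oracle on the corner cloud
  diag2 <- matrix(FALSE, 10, 10); diag2[1, 1] <- diag2[10, 10] <- TRUE
  expect_equal(as.numeric(convexHullArea(PlantMask(diag2))),
               hullAreaOracle(diag2))
  expect_error(convexHullArea(PlantMask(matrix(FALSE, 4, 4))),
               "no foreground")
})

test_that("hull area >= projected area; equality for convex solids", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(runif(400) < 0.2, 20, 20)
    if (!any(m)) next
    expect_gte(as.numeric(convexHullArea(PlantMask(m))) + 1e-9,
               as.numeric(projectedArea(PlantMask(m))))
  }
  rect <- matrix(FALSE, 12, 12); rect[3:9, 4:8] <- TRUE
  expect_equal(as.numeric(convexHullArea(PlantMask(rect))),
               as.numeric(projectedArea(PlantMask(rect))))
})

test_that("traits are invariant under mask translation", {
  set.seed(13)
  base <- matrix(FALSE, 30, 30)
  base[5:12, 6:10] <- matrix(runif(40) < 0.7, 8, 5)
  base[8, 8] <- TRUE
  ref <- list(p = as.numeric(projectedArea(PlantMask(base))),
              h = as.numeric(convexHullArea(PlantMask(base))),
              e = boundingExtent(PlantMask(base)))
  for (off in list(c(3, 2), c(10, 15), c(0, 9))) {
    shifted <- matrix(FALSE, 30, 30)
    idx <- which(base, arr.ind = TRUE)
    shifted[cbind(idx[, 1] + off[1], idx[, 2] + off[2])] <- TRUE
    expect_equal(as.numeric(projectedArea(PlantMask(shifted))), ref$p)
    expect_equal(as.numeric(convexHullArea(PlantMask(shifted))), ref$h)
    expect_equal(as.numeric(boundingExtent(PlantMask(shifted))),
                 as.numeric(ref$e))
  }
})

test_that("bounding extents come from foreground coordinate ranges", {
  one <- matrix(FALSE, 6, 6); one[4, 2] <- TRUE
  expect_equal(as.numeric(boundingExtent(PlantMask(one))), c(1, 1))
  rect <- matrix(FALSE, 10, 10); rect[2:6, 3:5] <- TRUE
  expect_equal(as.numeric(boundingExtent(PlantMask(rect))), c(5, 3))
  # L-shape spanning rows 2-11, cols 4-8: enumerate-and-range oracle
  L <- matrix(FALSE, 12, 12)
  L[2:11, 4] <- TRUE; L[11, 4:8] <- TRUE
  idx <- which(L, arr.ind = TRUE)
  expect_equal(as.numeric(boundingExtent(PlantMask(L))),
               c(diff(range(idx[, 1])) + 1, diff(range(idx[, 2])) + 1))
  expect_equal(as.numeric(boundingExtent(PlantMask(L))), c(10, 5))
})

test_that("trait series are sorted, complete and reject duplicates", {
  sc <- plantImageScenario(seed = 21, maxArea = 4000, view = "side")
  fix <- makePlantImages(sc, c(40, 25, 33))     # out of order on purpose
  imgs <- lapply(fix, function(x) x$image)
  ser <- buildTraitSeries(imgs)
  expect_equal(ser$dase, c(25, 33, 40))
  expect_true(all(diff(ser$hull_area) > 0))     # growing silhouettes
  expect_true(all(ser$projected_area <= ser$hull_area))
  expect_true(all(is.finite(ser$height)))       # side view has extents
  expect_true(all(ser$exg_mean > 0.3))          # green over the mask
  expect_equal(nrow(buildTraitSeries(imgs[1])), 1)
  expect_error(buildTraitSeries(c(imgs, imgs[2])), "duplicate")
})

test_that("whole-frame ExG mode is available and differs over soil", {
  sc <- plantImageScenario(seed = 3, maxArea = 3000)
  it <- makePlantImages(sc, 35)[[1]]
  masked <- buildTraitSeries(list(it$image), exgOverMask = TRUE)$exg_mean
  frame <- buildTraitSeries(list(it$image), exgOverMask = FALSE)$exg_mean
  expect_gt(masked, frame)   # soil pixels dilute the frame mean
})
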