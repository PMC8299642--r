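test_that("NIfTI volumes and label maps round-trip losslessly", {
  set.seed(5)
  lm <- TuberLabelMap(array(sample(0:6, 32^3, TRUE), c(32, 32, 32)),
                      voxelSize = c(1.1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  saveLabelmap(lm, f)
  back <- loadLabelmap(f)
  expect_identical(labelData(back), labelData(lm))
  expect_equal(voxelSize(back), c(1.1, 1, 1), tolerance = 1e-6)
  # header spacing flows into loadVolume; explicit argument wins + warns
  v <- loadVolume(f)
  expect_equal(voxelSize(v), c(1.1, 1, 1), tolerance = 1e-6)
  expect_warning(v2 <- loadVolume(f, voxelSize = c(2, 1, 1)), "overrides")
  expect_equal(voxelSize(v2), c(2, 1, 1))
})

test_that("TIFF stacks load but require an explicit voxel size", {
  arr <- array(runif(16 * 8 * 8), c(16, 8, 8))
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(seq_len(16), function(z) arr[z, , ]), f,
                  bits.per.sample = 32L)
  expect_error(loadVolume(f), "voxelSize")
  v <- loadVolume(f, voxelSize = c(1.1, 1, 1))
  expect_equal(dim(volumeData(v)), c(16, 8, 8))
  expect_equal(volumeData(v), arr, tolerance = 1e-6)
})

test_that("connected components agree with the graph-based oracle", {
  set.seed(99)
  for (i in 1:30) {
    a <- array(runif(20^3) < runif(1, 0.05, 0.5), c(20, 20, 20))
    for (conn in c(6, 26)) {
      got <- labelAndCount(a, conn)
      ref <- componentsOracle(a, conn)
      expect_equal(got$count, ref$count)
      expect_equal(sort(as.integer(got$sizes)), ref$sizes)
    }
  }
})

test_that("corner-touching blobs split under 6- but not 26-connectivity", {
  a <- array(0L, c(5, 5, 5))
  a[1:2, 1:2, 1:2] <- 1L
  a[3, 3, 3] <- 1L               # touches the cube only at a corner
  expect_equal(labelAndCount(a, 26)$count, 1)
  expect_equal(labelAndCount(a, 6)$count, 2)
  # two blobs separated by >= 2 voxels of background
  b <- array(0L, c(9, 9, 9))
  b[1:2, 1:2, 1] <- 1L; b[7:9, 7:8, 9] <- 1L
  lc <- labelAndCount(b, 26)
  expect_equal(lc$count, 2)
  expect_equal(sort(as.integer(lc$sizes)), c(4, 6))
  expect_equal(labelAndCount(array(0L, c(4, 4, 4)))$count, 0)
})

test_that("voxel tallies conserve the total foreground", {
  set.seed(31)
  a <- array(runif(18^3) < 0.3, c(18, 18, 18))
  lc <- labelAndCount(a, 26)
  expect_equal(sum(lc$sizes), sum(a))
  expect_equal(sum(lc$labels > 0), sum(a))
})

test_that("region growing recovers a bright ellipsoid (Dice >= 0.95)", {
  set.seed(11)
  d <- c(30, 36, 36)
  zc <- (0:29) * 1.1; yc <- 0:35; xc <- 0:35
  truth <- outer(outer(((zc - 16) / 9)^2, ((yc - 17) / 11)^2, "+"),
                 ((xc - 17) / 8)^2, "+") <= 1
  vol <- array(50 + rnorm(prod(d), sd = 5), d)
  vol[truth] <- 200 + rnorm(sum(truth), sd = 5)
  seeds <- array(0L, d)
  seeds[14:16, 15:19, 15:19] <- 1L
  lm <- regionGrow(Volume3D(vol, voxelSize = c(1.1, 1, 1)), seeds, k = 2.5)
  expect_gte(diceCoef(labelData(lm) == 1, truth), 0.95)
  expect_equal(lm@provenance, "seeded")
})

test_that("disjoint bright spheres grow into disjoint labels", {
  set.seed(12)
  d <- c(24, 40, 24)
  yc <- 0:39
  s1 <- outer(outer(((0:23) - 11)^2, (yc - 10)^2, "+"), ((0:23) - 11)^2,
              "+") <= 36
  s2 <- outer(outer(((0:23) - 11)^2, (yc - 29)^2, "+"), ((0:23) - 11)^2,
              "+") <= 36
  vol <- array(50 + rnorm(prod(d), 0, 5), d)
  vol[s1 | s2] <- 200 + rnorm(sum(s1 | s2), 0, 5)
  seeds <- array(0L, d)
  seeds[11:12, 9:11, 11:12] <- 1L
  seeds[11:12, 28:30, 11:12] <- 2L
  lab <- labelData(regionGrow(Volume3D(vol), seeds))
  expect_setequal(setdiff(unique(as.integer(lab)), 0L), c(1L, 2L))
  expect_gte(diceCoef(lab == 1, s1), 0.95)
  expect_gte(diceCoef(lab == 2, s2), 0.95)
})

test_that("degenerate seeds grow over uniform regions; empty seeds error", {
  vol <- Volume3D(array(100, c(6, 6, 6)))
  seeds <- array(0L, c(6, 6, 6)); seeds[3, 3, 3] <- 1L
  lab <- labelData(regionGrow(vol, seeds))
  expect_true(all(lab == 1L))    # uniform volume: whole region matches
  expect_error(regionGrow(vol, array(0L, c(6, 6, 6))), "empty")
  # seed on background surrounded by a different intensity: stays put
  v2 <- array(200, c(7, 7, 7)); v2[4, 4, 4] <- 50
  s2 <- array(0L, c(7, 7, 7)); s2[4, 4, 4] <- 1L
  expect_warning(lm2 <- regionGrow(Volume3D(v2), s2), "background")
  expect_equal(sum(labelData(lm2) == 1L), 1)
})

test_that("tuber measurements follow the voxel calibration exactly", {
  a <- array(0L, c(20, 20, 20)); a[1:10, 1:10, 1:10] <- 1L
  m <- measureTubers(TuberLabelMap(a, voxelSize = c(1.1, 1, 1)))
  expect_equal(m$volume_cm3, 1000 * 1.1 / 1000)   # 1000 voxels -> 1.1 cm^3
  expect_equal(m$eq_diameter_mm, (6 * 1100 / pi)^(1 / 3))
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  ms <- measureTubers(TuberLabelMap(single, voxelSize = c(1.1, 1, 1)))
  expect_equal(ms$volume_cm3, 0.0011)
  expect_equal(ms$eq_diameter_mm, (6 * 1.1 / pi)^(1 / 3))
  expect_equal(c(ms$cz, ms$cy, ms$cx), c(1.1, 1, 1))  # 0-based centres
  # doubling dz doubles every volume
  m2 <- measureTubers(TuberLabelMap(a, voxelSize = c(2.2, 1, 1)))
  expect_equal(m2$volume_cm3, 2 * m$volume_cm3)
})

test_that("digitised spheres recover the analytic volume within 5%", {
  for (r in c(5, 10, 15)) {
    m <- measureTubers(sphereLabelMap(r))
    expect_lt(abs(m$volume_cm3 - 4 / 3 * pi * r^3 / 1000) /
                (4 / 3 * pi * r^3 / 1000), 0.05)
    expect_lt(abs(m$eq_diameter_mm - 2 * r) / (2 * r), 0.02)
  }
})

test_that("the yield filter removes sub-15 mm finals and flags sub-3 mm", {
  rec <- function(id, dase, diam)
    data.frame(tuber_id = id, dase = dase, eq_diameter_mm = diam)
  recs <- rbind(rec(1, 32, 4), rec(1, 73, 16),
                rec(2, 32, 9), rec(2, 73, 14),
                rec(3, 32, 2.5), rec(3, 73, 15.0))
  out <- filterTubers(recs)
  expect_false(2 %in% out$records$tuber_id)       # 14 mm final: excluded
  expect_true(all(c(1, 3) %in% out$records$tuber_id))
  expect_equal(out$exclusions$tuber_id, 2)
  # exactly 15.0 mm is retained ("under 15 mm" is strict)
  expect_true(3 %in% out$records$tuber_id)
  # early sessions of retained tubers are kept even when small
  expect_equal(sum(out$records$tuber_id == 1), 2)
  expect_true(out$records$subdetectable[out$records$tuber_id == 3 &
                                          out$records$dase == 32])
  expect_error(filterTubers(rbind(rec(1, 32, 5), rec(1, 73, 20),
                                  rec(4, 32, 6))), "final session")
})

test_that("tracking matches by proximity, ranks by final volume", {
  rec <- function(id, dase, v, z, y, x)
    data.frame(tuber_id = id, dase = dase, volume_cm3 = v,
               eq_diameter_mm = (6000 * v / pi)^(1 / 3),
               cz = z, cy = y, cx = x)
  s1 <- rbind(rec(1, 32, 5, 10, 10, 10), rec(2, 32, 2, 40, 40, 40))
  s2 <- rbind(rec(1, 39, 9, 11, 10, 10), rec(2, 39, 4, 40, 41, 40))
  s3 <- rbind(rec(1, 73, 40.2, 11, 10, 10), rec(2, 73, 17.0, 40, 41, 41),
              rec(3, 73, 5.0, 70, 70, 70))
  tr <- trackTubers(rbind(s1, s2, s3))
  expect_equal(nrow(tr$ranking), 3)
  expect_equal(tr$ranking$final_volume_cm3, c(40.2, 17.0, 5.0))
  expect_equal(tr$ranking$tuber_label, sprintf("Tuber-%02d", 1:3))
  # tuber appearing only at the final session opens a fresh track
  newcomer <- tr$growth[tr$growth$tuber_label == "Tuber-03", ]
  expect_equal(newcomer$dase, 73)
  long <- tr$growth[tr$growth$tuber_label == "Tuber-01", ]
  expect_equal(long$volume_cm3, c(5, 9, 40.2))
})

test_that("competing matches resolve to the nearer tuber", {
  rec <- function(id, dase, v, z, y, x)
    data.frame(tuber_id = id, dase = dase, volume_cm3 = v,
               cz = z, cy = y, cx = x)
  s1 <- rec(1, 32, 5, 20, 20, 20)
  s2 <- rbind(rec(1, 39, 6, 22, 20, 20),   # 2 mm away: wins
              rec(2, 39, 3, 30, 20, 20))   # 10 mm away: new track
  tr <- trackTubers(rbind(s1, s2), radius = 15)
  expect_equal(nrow(tr$ranking), 2)
  expect_equal(tr$growth$volume_cm3[tr$growth$track_id == 1], c(5, 6))
  expect_true("new-track" %in% tr$log$action)
})

test_that("condition summaries carry Tukey letters when replicated", {
  set.seed(71)
  mk <- function(plant, cond, scale) do.call(rbind, lapply(c(32, 39), function(d)
    data.frame(plant_id = plant, condition = cond, dase = d,
               volume_cm3 = scale * runif(5, 1, 3) * d / 32)))
  recs <- rbind(mk("p1", "Control", 1), mk("p2", "Control", 1.1),
                mk("p3", "Control", 0.9),
                mk("q1", "MWD", 3), mk("q2", "MWD", 3.2), mk("q3", "MWD", 2.8))
  s <- summarizeConditions(recs)
  expect_true(all(c("Control", "MWD") %in% s$condition))
  at32 <- s[s$dase == 32, ]
  expect_equal(at32$mean_count, c(5, 5))            # same tuber counts
  expect_equal(at32$letter_count[1], at32$letter_count[2])
  expect_false(at32$letter_volume[1] == at32$letter_volume[2])  # 3x volumes
  # single plant per condition: letters suppressed
  s1 <- summarizeConditions(rbind(mk("p1", "Control", 1), mk("q1", "MWD", 3)))
  expect_true(all(is.na(s1$letter_volume)))
})
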