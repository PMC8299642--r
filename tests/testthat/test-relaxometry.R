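test_that("simulated decays follow the multi-exponential model exactly", {
  d <- simulateCpmg(cbind(100, 1), tau = 0.2, nEchoes = 2000,
                    noiseSigma = 0)
  expect_equal(echoTimes(d), 2 * 0.2 * (1:2000))
  expect_equal(amplitudes(d), exp(-echoTimes(d) / 100))
  comp <- cbind(c(40, 400), c(0.4, 0.6))
  db <- simulateCpmg(comp, tau = 0.2, nEchoes = 10, noiseSigma = 0)
  expect_equal(amplitudes(db), decayOracle(comp, echoTimes(db)))
  expect_equal(amplitudes(db)[1],
               0.4 * exp(-0.4 / 40) + 0.6 * exp(-0.4 / 400))
})

test_that("decay simulation is reproducible by seed and leaves the RNG alone", {
  a <- simulateCpmg(cbind(100, 1), nEchoes = 50, noiseSigma = 1e-2, seed = 9)
  b <- simulateCpmg(cbind(100, 1), nEchoes = 50, noiseSigma = 1e-2, seed = 9)
  expect_identical(amplitudes(a), amplitudes(b))
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(simulateCpmg(cbind(50, 1), nEchoes = 10,
                                        noiseSigma = 1e-2, seed = 1))
  expect_identical(runif(5), before)
  expect_error(simulateCpmg(cbind(-5, 1)), "positive")
  expect_error(simulateCpmg(cbind(5, 1), tau = 0), "positive")
})

test_that("MEM recovers a noiseless single exponential", {
  d <- simulateCpmg(cbind(100, 1), tau = 0.2, nEchoes = 2000, noiseSigma = 0)
  fit <- invertMem(d)
  expect_true(all(t2Density(fit) >= 0))
  pk <- findPeaks(fit)
  expect_equal(nrow(pk), 1)
  grid <- t2Values(fit)
  step <- grid[2] / grid[1]
  expect_lt(abs(log(pk$t2_mode / 100)), log(step) * 1.001)  # within 1 grid step
  expect_lt(abs(sum(t2Density(fit)) - 1), 0.02)             # area 1 +/- 2%
})

test_that("both solvers conserve total area + offset on noiseless decays", {
  for (comp in list(cbind(100, 1), cbind(c(40, 400), c(0.4, 0.6)))) {
    d <- simulateCpmg(comp, tau = 0.2, nEchoes = 3000, noiseSigma = 0)
    s0 <- sum(comp[, 2])
    for (fit in list(invertMem(d), invertNnls(d))) {
      expect_lt(abs(sum(t2Density(fit)) + baselineOffset(fit) - s0) / s0,
                0.03)
    }
  }
})

test_that("Tikhonov-NNLS recovers a noiseless single exponential", {
  d <- simulateCpmg(cbind(100, 1), tau = 0.2, nEchoes = 2000, noiseSigma = 0)
  fit <- invertNnls(d)
  pk <- findPeaks(fit)
  expect_equal(nrow(pk), 1)
  step <- t2Values(fit)[2] / t2Values(fit)[1]
  expect_lt(abs(log(pk$t2_mode / 100)), log(step) * 1.001)
  # lambda = 0 on an exactly representable signal: near-zero residual
  grid <- t2Grid()
  onGrid <- simulateCpmg(cbind(grid[120], 1), tau = 0.2, nEchoes = 1500,
                         noiseSigma = 0)
  f0 <- invertNnls(onGrid, grid, lambda = 0)
  recon <- as.vector(exp(-outer(echoTimes(onGrid), 1 / grid)) %*%
                       t2Density(f0)) + baselineOffset(f0)
  expect_lt(max(abs(recon - amplitudes(onGrid))), 1e-8)
  expect_error(invertNnls(d, lambda = -1), ">= 0")
})

test_that("bi-exponential recovery at SNR 1000 hits modes and fractions", {
  for (seed in c(3, 17, 28)) {
    d <- simulateCpmg(cbind(c(40, 400), c(0.4, 0.6)), tau = 0.2,
                      nEchoes = 5000, noiseSigma = 1e-3, seed = seed)
    for (fit in list(invertMem(d), invertNnls(d))) {
      pk <- findPeaks(fit)
      expect_equal(nrow(pk), 2)
      expect_lt(abs(pk$t2_mode[1] - 40) / 40, 0.10)
      expect_lt(abs(pk$t2_mode[2] - 400) / 400, 0.10)
      expect_lt(abs(pk$area_fraction[1] - 0.4), 0.05)
      expect_lt(abs(pk$area_fraction[2] - 0.6), 0.05)
      expect_gte(fitChisq(fit), 0.8)
      expect_lte(fitChisq(fit), 1.2)
    }
  }
})

test_that("components closer than the resolution limit merge into one peak", {
  d <- simulateCpmg(cbind(c(100, 150), c(0.5, 0.5)), tau = 0.2,
                    nEchoes = 3000, noiseSigma = 1e-3, seed = 3)
  expect_equal(nrow(findPeaks(invertMem(d))), 1)
  expect_equal(nrow(findPeaks(invertNnls(d))), 1)
})

test_that("zero-amplitude decays invert to empty distributions", {
  z <- CpmgDecay(c(0.4, 0.8, 1.2), c(0, 0, 0), noiseSigma = 1e-3)
  for (fit in list(invertMem(z), invertNnls(z))) {
    expect_true(all(t2Density(fit) == 0))
    expect_equal(nrow(findPeaks(fit)), 0)
  }
})

test_that("the tail estimator recovers an unstated noise level", {
  d <- simulateCpmg(cbind(30, 1), tau = 0.2, nEchoes = 4000,
                    noiseSigma = 5e-3, seed = 4)
  blind <- CpmgDecay(echoTimes(d), amplitudes(d))   # sigma withheld
  fit <- invertMem(blind)
  pk <- findPeaks(fit)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$t2_mode - 30) / 30, 0.10)
})

test_that("findPeaks locates maxima, bounds and applies the area filter", {
  grid <- t2Grid(100)
  bump <- function(center, width, h)
    h * exp(-(log(grid / center))^2 / (2 * width^2))
  # single bump centred at 100 ms
  d1 <- new("T2Distribution", t2 = grid, density = bump(100, 0.15, 1),
            offset = 0, chisqPerEcho = 1, solver = "mem")
  p1 <- findPeaks(d1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$t2_mode, grid[which.max(t2Density(d1))])
  # two bumps with a valley: bounds at the brute-force minimum between them
  dens <- bump(10, 0.12, 1) + bump(300, 0.12, 0.8)
  d2 <- new("T2Distribution", t2 = grid, density = dens, offset = 0,
            chisqPerEcho = 1, solver = "mem")
  p2 <- findPeaks(d2)
  expect_equal(nrow(p2), 2)
  between <- which(grid > p2$t2_mode[1] & grid < p2$t2_mode[2])
  valley <- between[which.min(dens[between])]
  expect_equal(p2$right[1], valley)
  expect_equal(p2$left[2], valley + 1)
  expect_true(all(diff(p2$t2_mode) > 0))
  expect_lte(sum(p2$area_fraction), 1 + 1e-12)
  # sub-threshold bump excluded
  dens3 <- bump(100, 0.12, 1) + bump(1000, 0.05, 0.004)
  d3 <- new("T2Distribution", t2 = grid, density = dens3, offset = 0,
            chisqPerEcho = 1, solver = "mem")
  expect_equal(nrow(findPeaks(d3, minAreaFraction = 0.01)), 1)
})

test_that("vacuolar assignment follows the dominance rule", {
  pk <- function(modes, fracs)
    data.frame(t2_mode = modes, area = fracs, area_fraction = fracs,
               left = 1, right = 2, left_t2 = 1, right_t2 = 2)
  a1 <- assignVacuolar(pk(c(5, 300), c(0.1, 0.9)))
  expect_equal(names(a1$labels), "vt")
  expect_equal(unname(a1$labels["vt"]), 300)
  a2 <- assignVacuolar(pk(c(5, 200, 600), c(0.1, 0.45, 0.45)))
  expect_equal(names(a2$labels), c("vs", "vl"))
  expect_equal(unname(a2$labels), c(200, 600))
  expect_gt(a2$labels["vl"], a2$labels["vs"])
  a3 <- assignVacuolar(pk(250, 1))
  expect_equal(names(a3$labels), "vt")
  # below-floor or low-fraction peaks never become vs/vl
  a4 <- assignVacuolar(pk(c(5, 20, 500), c(0.3, 0.3, 0.4)))
  expect_equal(names(a4$labels), "vt")
  expect_error(assignVacuolar(data.frame()), "at least one")
})

test_that("split/merge events are read off component-count transitions", {
  e1 <- detectSplitMerge(c(24, 32, 39, 46), c(1, 1, 2, 2))
  expect_equal(e1$event, "split")
  expect_equal(e1$dase, 39)
  # the old-leaf merge/split/re-merge sequence at 39/46/60
  e2 <- detectSplitMerge(c(32, 39, 46, 60), c(2, 1, 2, 1))
  expect_equal(e2$event, c("merge", "split", "merge"))
  expect_equal(e2$dase, c(39, 46, 60))
  expect_equal(nrow(detectSplitMerge(c(10, 20, 30), c(1, 1, 1))), 0)
  expect_error(detectSplitMerge(c(30, 20), c(1, 2)), "increasing")
  expect_error(detectSplitMerge(39, 1), "two time points")
})

test_that("replicates average only within homogeneous partitions", {
  one <- function(t2) list(labels = c(vt = t2), nComponents = 1L)
  two <- function(vs, vl) list(labels = c(vs = vs, vl = vl),
                               nComponents = 2L)
  flat <- averageHomogeneous(list(one(98), one(100), one(102), one(104)))
  expect_equal(flat$mean_t2[flat$label == "vt"], 101)
  mixed <- averageHomogeneous(list(two(150, 420), two(160, 400),
                                   two(155, 410), one(260)))
  expect_equal(sort(unique(mixed$n_components)), c(1, 2))
  expect_equal(mixed$n_replicates[mixed$label == "vt"], 1)
  expect_true(is.na(mixed$sd_t2[mixed$label == "vt"]))
  expect_equal(mixed$mean_t2[mixed$label == "vs"], 155)
  expect_equal(mixed$mean_t2[mixed$label == "vl"], 410)
  expect_equal(mixed$n_replicates[mixed$label == "vl"], 3)
  # minimum partition size filter
  filt <- averageHomogeneous(list(two(150, 420), two(160, 400), one(260)),
                             minSize = 2)
  expect_false("vt" %in% filt$label)
})
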