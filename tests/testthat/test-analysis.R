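# Binning, the 95 % rule, spectra, variability, rates.

test_that("binning uses left-closed right-open bins and conserves spikes", {
  g <- networkGeometry(1, 1, 4, 4)
  sp <- data.frame(t = c(0.2, 0.9, 1.0), Q = "E", j = 1L, k = 1L,
                   l = c(1L, 2L, 3L), id = 1:3, instant = NA_integer_)
  r <- new("SpikeRaster", spikes = sp, duration = 2, geometry = g,
           seed = NA_real_)
  cnt <- binSpikes(r, 1)
  expect_equal(unname(cnt[, "E.1.1"]), c(2, 1))
  # bin equal to the duration: one bin holding everything
  cnt1 <- binSpikes(r, 2)
  expect_equal(unname(cnt1[, "E.1.1"]), 3)
  # conservation on a random raster
  pr <- makePlantedRaster(plantedRasterSpec(nE = 16, nI = 16, nullRate = 40,
                                            duration = 500, seed = 3))
  cnt2 <- binSpikes(pr$raster, 1)
  expect_identical(sum(cnt2), nSpikes(pr$raster))
})

test_that("the binomial cutoff matches exact CDF enumeration", {
  # zero rate: cutoff 0, so any spike flags the bin
  expect_identical(mfeCutoff(128, 0, 1), 0L)
  # enumeration oracle: smallest c with P(X <= c) >= 0.95, X ~ Bin(n, p)
  enumCutoff <- function(n, p, perc = 0.95) {
    cdf <- cumsum(dbinom(0:n, n, p))
    (0:n)[which(cdf >= perc)[1]]
  }
  expect_identical(mfeCutoff(128, 5, 1), enumCutoff(128, 5 / 1000))
  expect_identical(mfeCutoff(128, 5, 1), 2L)
  for (rate in c(1, 12, 40)) for (bin in c(1, 2, 5))
    expect_identical(mfeCutoff(128, rate, bin),
                     enumCutoff(128, min(1, rate * bin / 1000)))
  expect_error(mfeCutoff(128, 5, 1, percentile = 1), "percentile")
})

test_that("a count exactly at the cutoff is not an MFE-bin", {
  cnt <- matrix(c(0, 2, 3, 2, 5), ncol = 1,
                dimnames = list(NULL, "E.1.1"))
  attr(cnt, "binMs") <- 1
  ev <- detectMFEs(cnt, cutoff = 2)
  expect_equal(ev$bin, c(3, 5))      # strictly greater than the cutoff only
  expect_equal(ev$magnitude, c(3, 5))
})

test_that("detector is calibrated on the homogeneous Poisson null", {
  # flagged-bin fraction stays at/below the null tail mass + 3 sigma
  nullRate <- 5; nN <- 128; dur <- 4000
  p <- nullRate / 1000
  cutoff <- mfeCutoff(nN, nullRate, 1)
  tailMass <- 1 - pbinom(cutoff, nN, p)
  fr <- vapply(1:20, function(s) {
    pr <- makePlantedRaster(plantedRasterSpec(nE = nN, nI = 0,
                                              nullRate = nullRate,
                                              duration = dur, seed = s))
    cnt <- binSpikes(pr$raster, 1)
    mean(cnt[, 1] > cutoff)
  }, numeric(1))
  se <- sqrt(tailMass * (1 - tailMass) / dur)
  expect_true(all(fr <= 0.05 + 3 * se))
  expect_lt(mean(fr), tailMass + 3 * se / sqrt(20))
})

test_that("planted synchronous events are recovered exactly", {
  ev <- data.frame(t = c(500.2, 1500.7, 2800.4), sizeE = 30L, sizeI = 0L)
  pr <- makePlantedRaster(plantedRasterSpec(nE = 128, nI = 0, nullRate = 3,
                                            duration = 4000, events = ev,
                                            seed = 4))
  cnt <- binSpikes(pr$raster, 1)
  cutoff <- mfeCutoff(128, sum(cnt) / 128 / 4, 1)
  det <- detectMFEs(cnt[, "E.1.1", drop = FALSE], cutoff)
  # all three planted bins found
  expect_true(all(floor(ev$t) %in% (det$bin - 1L)))
  # and essentially nothing else (null false-positive rate)
  tailMass <- 1 - pbinom(cutoff, 128, sum(cnt) / 128 / 4 / 1000)
  expect_lte(nrow(det) - 3, 3 * (tailMass * 4000 + 3 * sqrt(tailMass * 4000)))
  # empty raster: empty event list
  pr0 <- makePlantedRaster(plantedRasterSpec(nE = 8, nI = 0, nullRate = 0,
                                             duration = 100, seed = 1))
  expect_identical(nrow(detectMFEs(binSpikes(pr0$raster, 1), 0)), 0L)
})

test_that("MFE spike fraction behaves as a homogeneity measure", {
  # all spikes in one giant bin above cutoff: fraction 1
  cnt <- matrix(c(0, 50, 0), ncol = 1, dimnames = list(NULL, "E.1.1"))
  expect_equal(unname(mfeSpikeFraction(cnt, 2)["total"]), 1)
  # homogeneous raster: small fraction, decreasing as percentile -> 1
  pr <- makePlantedRaster(plantedRasterSpec(nE = 128, nI = 0, nullRate = 8,
                                            duration = 4000, seed = 6))
  cnt2 <- binSpikes(pr$raster, 1)
  rate <- sum(cnt2) / 128 / 4
  f95 <- mfeSpikeFraction(cnt2[, 1, drop = FALSE],
                          mfeCutoff(128, rate, 1, 0.95))["total"]
  f999 <- mfeSpikeFraction(cnt2[, 1, drop = FALSE],
                           mfeCutoff(128, rate, 1, 0.999))["total"]
  expect_lt(f95, 0.25)
  expect_lte(f999, f95)
  # zero spikes: fraction 0, not NaN
  expect_identical(unname(mfeSpikeFraction(matrix(0L, 5, 1), 0)["total"]), 0)
})

test_that("the LFP-proxy PSD finds injected structure", {
  g <- networkGeometry(1, 1, 2, 2)
  tt <- seq(1, 2048)
  mk <- function(x) {
    cm <- cbind(x, x); colnames(cm) <- c("E.1.1", "I.1.1")
    new("VoltageTrace", time = tt, clusterV = cm, fullV = NULL,
        geometry = g)
  }
  # constant trace: all power at DC
  psd <- lfpPSD(mk(rep(0.3, 2048)), windowMs = 512)
  expect_gt(psd$power[1], 0)
  expect_equal(max(psd$power[-1]), 0)
  # injected 40 Hz sinusoid: spectral peak in the 40 Hz bin
  x <- 0.3 + 0.1 * sin(2 * pi * 40 * tt / 1000)
  psd2 <- lfpPSD(mk(x), windowMs = 512)
  pk <- psd2$freq[which.max(psd2$power[-1]) + 1]
  expect_lt(abs(pk - 40), 1000 / 512)
  # shorter than one window: error
  short <- mk(rep(0, 2048))
  short@time <- tt[1:100]
  short@clusterV <- short@clusterV[1:100, , drop = FALSE]
  expect_error(lfpPSD(short, windowMs = 512), "window")
})

test_that("trial-to-trial CV matches the Poisson identity", {
  g <- networkGeometry(1, 1, 64, 1)
  mkTrial <- function(seed, lambda = 8) {
    pr <- makePlantedRaster(plantedRasterSpec(nE = 64, nI = 1,
                                              nullRate = lambda,
                                              duration = 1000, seed = seed))
    pr$raster
  }
  trials <- lapply(1:40, mkTrial)
  out <- trialCV(trials, window = c(0, 1000), population = "E")
  # counts ~ Poisson(8): CV ~ 1/sqrt(8)
  expect_equal(out$median, 1 / sqrt(8), tolerance = 0.15)
  # identical counts across trials: CV 0
  same <- lapply(1:5, function(s) mkTrial(1))
  expect_identical(trialCV(same, c(0, 1000), "E")$median, 0)
  expect_error(trialCV(trials, c(500, 1500)), "window")
})

test_that("rate decomposition is an exact partition of the total rate", {
  ev <- data.frame(t = c(600.5, 900.1), sizeE = 40L, sizeI = 35L)
  pr <- makePlantedRaster(plantedRasterSpec(nE = 128, nI = 128, nullRate = 6,
                                            duration = 3000, events = ev,
                                            seed = 8))
  rc <- rateCurves(list(x = pr$raster), cluster = c(1, 1), burnIn = 500)
  expect_equal(rc$rateI, rc$rateI_mfe + rc$rateI_nonmfe)
  expect_equal(rc$rateE, rc$rateE_mfe + rc$rateE_nonmfe)
  expect_gt(rc$rateI_mfe, 0)   # the planted barrages are MFE-spikes
})

test_that("estimators are invariant to raster record order", {
  pr <- makePlantedRaster(plantedRasterSpec(nE = 16, nI = 16, nullRate = 30,
                                            duration = 800, seed = 12))
  r1 <- pr$raster
  sp <- spikes(r1)
  perm <- withr::with_seed(1, sample.int(nrow(sp)))
  spShuf <- sp[perm, ]
  spShuf <- spShuf[order(spShuf$t), ]   # class invariant: sorted by t
  r2 <- new("SpikeRaster", spikes = spShuf, duration = r1@duration,
            geometry = r1@geometry, seed = r1@seed)
  expect_equal(binSpikes(r1, 1), binSpikes(r2, 1))
  x1 <- crossCovariance(r1, "E", "I", A = 1, B = 1, tauMax = 20, dt = 1)
  x2 <- crossCovariance(r2, "E", "I", A = 1, B = 1, tauMax = 20, dt = 1)
  expect_equal(x1@raw, x2@raw)
  expect_equal(x1@meanSub, x2@meanSub)
})
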