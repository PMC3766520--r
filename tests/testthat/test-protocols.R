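# Fixture generators, regimes, benchmark protocol plumbing.

test_that("planted rasters reproduce the homogeneous Poisson null", {
  spec <- plantedRasterSpec(nE = 64, nI = 0, nullRate = 20, duration = 10000,
                            seed = 5)
  pr <- makePlantedRaster(spec)
  expect_identical(nrow(pr$truth), 0L)
  n <- nSpikes(pr$raster)
  lam <- 64 * 20 * 10      # expected spike count
  expect_lt(abs(n - lam), 4 * sqrt(lam))
  # pooled spike times are uniform: chi-squared GOF over 20 bins
  ct <- table(cut(spikes(pr$raster)$t, seq(0, 10000, length.out = 21)))
  expect_gt(chisq.test(ct)$p.value, 0.01)
  # per-neuron counts are Poisson-dispersed (index of dispersion ~ 1)
  cnt <- tabulate(spikes(pr$raster)$id, nbins = 64)
  disp <- var(cnt) / mean(cnt)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / 63))
  # determinism
  pr2 <- makePlantedRaster(spec)
  expect_identical(spikes(pr2$raster), spikes(pr$raster))
})

test_that("planted events appear at their stated bins with stated sizes", {
  ev <- data.frame(t = c(100.5, 900.25, 2500), sizeE = c(30L, 64L, 10L),
                   sizeI = c(5L, 0L, 20L))
  spec <- plantedRasterSpec(nE = 64, nI = 32, nullRate = 2, duration = 3000,
                            events = ev, seed = 9)
  pr <- makePlantedRaster(spec)
  expect_identical(pr$truth, ev)
  sp <- spikes(pr$raster)
  for (z in seq_len(nrow(ev))) {
    atE <- sum(sp$t == ev$t[z] & sp$Q == "E")
    atI <- sum(sp$t == ev$t[z] & sp$Q == "I")
    expect_gte(atE, ev$sizeE[z]); expect_lte(atE - ev$sizeE[z], 2)
    expect_gte(atI, ev$sizeI[z])
  }
  # a planted event uses distinct neurons
  full <- sp[sp$t == 900.25 & sp$Q == "E", ]
  expect_identical(length(unique(full$id)), nrow(full))
  # size above N is rejected
  expect_error(plantedRasterSpec(nE = 8, nI = 8, nullRate = 1,
                                 duration = 100,
                                 events = data.frame(t = 1, sizeE = 9L,
                                                     sizeI = 0L)),
               "exceed")
})

test_that("regimes round-trip through YAML with checksum verification", {
  reg <- defaultRegime()
  expect_s4_class(reg, "Regime")
  f <- file.path(tempdir(), "regime-test.yaml")
  writeRegime(reg, f)
  reg2 <- loadRegime(f)
  expect_identical(reg2@connectivity@sFast, reg@connectivity@sFast)
  expect_identical(reg2@drive@etaBkgE, reg@drive@etaBkgE)
  expect_identical(reg2@checklist, reg@checklist)
  # a corrupted file is rejected
  txt <- readLines(f)
  txt <- sub("etaBkgE: .*", "etaBkgE: 123.0", txt)
  writeLines(txt, f)
  expect_error(loadRegime(f), "checksum")
})

test_that("shipped regimes satisfy the drive constraints", {
  for (nm in listRegimes()) {
    reg <- loadRegime(nm)
    expect_gte(reg@drive@etaBkgE, 250)
    expect_lte(reg@drive@etaBkgE, 500)
    ratio <- reg@drive@sDriveE / reg@connectivity@sFast["E", "E"]
    expect_gt(ratio, 0.3)
    expect_lt(ratio, 0.7)
  }
})

test_that("the single-cluster regime produces correlated E and I MFEs", {
  reg <- singleClusterRegime()
  net <- regimeNetwork(reg, seed = 3)
  res <- runSimulation(net, reg@drive, NULL,
                       simConfig(duration = 10000, seed = 12),
                       params = reg@neuron, kernels = reg@kernels)
  sp <- spikes(res)
  live <- sp$t >= 500
  # MFE-rich regime: per-instant E and I magnitudes positively correlated
  byI <- sp[live & !is.na(sp$instant), ]
  magE <- tapply(byI$Q == "E", byI$instant, sum)
  magI <- tapply(byI$Q == "I", byI$instant, sum)
  big <- magE + magI >= 2
  expect_gt(sum(big), 20)
  expect_gt(cor(magE[big], magI[big]), 0)
  # and a high MFE-spike fraction relative to the Poisson null
  cnt <- binSpikes(raster(res), 1)
  keep <- attr(cnt, "starts") >= 500
  rE <- sum(cnt[keep, "E.1.1"]) / 128 / 9.5
  frac <- mfeSpikeFraction(cnt[keep, "E.1.1", drop = FALSE],
                           mfeCutoff(128, rE, 1))["total"]
  expect_gt(unname(frac), 0.3)
})

test_that("contrast-size sweep echoes the standard contrast grid", {
  # metadata contract only (no simulation): defaults carry the four
  # standard contrasts
  expect_identical(eval(formals(contrastSizeSweep)$contrasts),
                   c(0.7500, 0.3750, 0.1875, 0.0938))
})

test_that("background protocol on a zero-coupling network is structureless", {
  reg <- defaultRegime()
  reg@connectivity <- connectivityParams(
    pFromE = 0.2, pFromI = 0.5,
    sFast = matrix(0, 2, 2), sSlow = c(0, 0),
    lFast = c(0, 0), lSlow = c(0, 0))
  reg@drive <- driveParams(etaBkgE = 450, etaBkgI = 450,
                           sDriveE = 0.68, sDriveI = 0.68)
  bg <- backgroundProtocol(reg, duration = 3000, seed = 2, tauMax = 100)
  # independent neurons: no sustained orientation dominance beyond chance
  expect_true(nrow(bg$episodes) <= 2)
  # mean-subtracted cross-covariance flat at the independent-neuron scale
  x <- bg$xcov[["C.E.E.A1.B0"]]
  rate <- bg$rates["E"] / 1000
  sdNull <- sqrt(x@meta$nPairs * x@meta$T) * rate * (1 - rate)
  expect_lt(max(abs(x@meanSub)), 5 * sdNull)
})
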