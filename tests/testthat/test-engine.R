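# The hybrid event-driven / substep simulation loop.

test_that("zero drive produces zero spikes", {
  net <- smallTestNetwork()
  dr <- driveParams(etaBkgE = 0, etaBkgI = 0)
  res <- runSimulation(net, dr, NULL, simConfig(duration = 500, seed = 1))
  expect_identical(nSpikes(res), 0L)
})

test_that("runs are bit-reproducible given the configuration", {
  net <- smallTestNetwork()
  dr <- driveParams(etaBkgE = 400, etaBkgI = 400, sDriveE = 0.6,
                    sDriveI = 0.55)
  cfg <- simConfig(duration = 1500, seed = 42, sampleInterval = 1,
                   sampleMode = "cluster")
  r1 <- runSimulation(net, dr, NULL, cfg)
  r2 <- runSimulation(net, dr, NULL, cfg)
  expect_identical(spikes(r1), spikes(r2))
  expect_identical(voltageTrace(r1)@clusterV, voltageTrace(r2)@clusterV)
  r3 <- runSimulation(net, dr, NULL, simConfig(duration = 1500, seed = 43))
  expect_false(identical(spikes(r1)$t, spikes(r3)$t))
})

test_that("single-neuron firing matches an independent renewal oracle", {
  # one E neuron, no recurrence: every drive arrival jumps the voltage by
  # the exact delta rule; the engine's ISI statistics must match a direct
  # Monte Carlo of that renewal process
  g1 <- networkGeometry(1, 1, 1, 1)
  cv0 <- connectivityParams(pFromE = 0, pFromI = 0,
                            sFast = matrix(0, 2, 2), sSlow = c(0, 0),
                            lFast = c(0, 0), lSlow = c(0, 0))
  net <- buildNetwork(g1, cv0, seed = 1)
  dr <- driveParams(etaBkgE = 500, etaBkgI = 0, sDriveE = 0.65, sDriveI = 0)
  res <- runSimulation(net, dr, NULL, simConfig(duration = 20000, seed = 5))
  sp <- spikes(res)
  isi <- diff(sp$t[sp$Q == "E"])

  p <- neuronParams()
  oracle <- withr::with_seed(99, {
    t <- 0; V <- 0; ref <- -Inf; times <- numeric(0)
    while (t < 20000) {
      tn <- t + rexp(1, 0.5)
      if (tn < 20000 && tn > ref) {
        tstart <- max(t, ref)
        V <- V * exp(-(tn - tstart) / 20)
        V <- p@VE + (V - p@VE) * exp(-0.65 / 20)
        if (V >= 1) { times <- c(times, tn); V <- 0; ref <- tn + 1 }
      }
      t <- tn
    }
    times
  })
  isiO <- diff(oracle)
  expect_equal(mean(isi), mean(isiO), tolerance = 0.05)
  expect_equal(sd(isi), sd(isiO), tolerance = 0.12)
  expect_equal(length(isi), length(isiO), tolerance = 0.05)
})

test_that("raster invariants hold on a recurrent driven run", {
  net <- smallTestNetwork()
  dr <- driveParams(etaBkgE = 400, etaBkgI = 400, sDriveE = 0.62,
                    sDriveI = 0.5)
  res <- runSimulation(net, dr, NULL,
                       simConfig(duration = 2000, seed = 7,
                                 sampleInterval = 1, sampleMode = "full"))
  sp <- spikes(res)
  expect_gt(nrow(sp), 0)
  expect_false(is.unsorted(sp$t))
  expect_true(all(sp$t >= 0 & sp$t <= 2000))
  # per-neuron inter-spike gaps respect the refractory period
  # (cascade-internal ties share one t, but one neuron never repeats)
  gaps <- tapply(sp$t, sp$id, function(tt) if (length(tt) > 1) min(diff(tt))
                 else Inf)
  expect_true(all(gaps >= 1))
  # voltages stay in [V_I, V_T]
  fv <- voltageTrace(res)@fullV
  expect_gte(min(fv), -2 / 3 - 1e-12)
  expect_lte(max(fv), 1)
})

test_that("spikes in one cascade instant share a time and are causally keyed", {
  net <- smallTestNetwork()
  dr <- driveParams(etaBkgE = 450, etaBkgI = 450, sDriveE = 0.62,
                    sDriveI = 0.5)
  res <- runSimulation(net, dr, NULL, simConfig(duration = 2000, seed = 9))
  sp <- spikes(res)
  byInstant <- split(sp, sp$instant)
  expect_true(all(vapply(byInstant, function(d) length(unique(d$t)) == 1,
                         logical(1))))
  expect_true(all(vapply(byInstant, function(d) !anyDuplicated(d$id),
                         logical(1))))
})

test_that("halving the substep barely changes the spike count", {
  net <- smallTestNetwork()
  dr <- driveParams(etaBkgE = 420, etaBkgI = 420, sDriveE = 0.6,
                    sDriveI = 0.5)
  n1 <- nSpikes(runSimulation(net, dr, NULL,
                              simConfig(duration = 10000, seed = 3,
                                        substep = 0.1)))
  n2 <- nSpikes(runSimulation(net, dr, NULL,
                              simConfig(duration = 10000, seed = 3,
                                        substep = 0.05)))
  expect_lt(abs(n1 - n2) / n1, 0.005)
})

test_that("finite fast kernels keep MFE-like events detectable", {
  # tau_fast ~ 2 ms: cascades are no longer single instants, but the MFE-bin
  # fraction must stay above the 5 % null level in an MFE regime
  reg <- singleClusterRegime()
  net <- regimeNetwork(reg, seed = 2)
  res <- runSimulation(net, reg@drive, NULL,
                       simConfig(duration = 4000, seed = 4),
                       params = reg@neuron,
                       kernels = synapticKernels(tauSlow = 128,
                                                 tauFastE = 2, tauFastI = 2))
  sp <- spikes(res)
  live <- sp$t >= 500
  rE <- sum(live & sp$Q == "E") / 128 / 3.5
  cnt <- binSpikes(raster(res), 1)
  keep <- attr(cnt, "starts") >= 500
  cutE <- mfeCutoff(128, rE, 1)
  fracFlagged <- mean(cnt[keep, "E.1.1"] > cutE)
  nullTail <- 1 - pbinom(cutE, 128, rE / 1000)
  expect_gt(fracFlagged, nullTail + 3 * sqrt(nullTail / sum(keep)))
})

test_that("horizontal delays postpone long-range deliveries without breaking the run", {
  g <- networkGeometry(2, 1, 24, 24)
  cvD <- connectivityParams(delay = 10)
  netD <- buildNetwork(g, cvD, seed = 3)
  dr <- driveParams(etaBkgE = 420, etaBkgI = 420, sDriveE = 0.6,
                    sDriveI = 0.5)
  resD <- runSimulation(netD, dr, NULL, simConfig(duration = 2000, seed = 6))
  expect_gt(nSpikes(resD), 0)
  sp <- spikes(resD)
  gaps <- tapply(sp$t, sp$id, function(tt) if (length(tt) > 1) min(diff(tt))
                 else Inf)
  expect_true(all(gaps >= 1))
})

test_that("trials share the configuration but differ by seed", {
  net <- smallTestNetwork()
  dr <- driveParams(etaBkgE = 420, etaBkgI = 420, sDriveE = 0.6,
                    sDriveI = 0.5)
  cfg <- simConfig(duration = 800, seed = 1)
  tr <- runTrials(net, dr, NULL, cfg, seeds = c(11, 12))
  expect_length(tr, 2)
  expect_false(identical(spikes(tr[[1]])$t, spikes(tr[[2]])$t))
  # a single trial equals a direct run with that seed
  cfg1 <- cfg; cfg1@seed <- 11
  expect_identical(spikes(tr[[1]]), spikes(runSimulation(net, dr, NULL, cfg1)))
  expect_warning(runTrials(net, dr, NULL, cfg, seeds = c(5, 5)), "duplicate")
})

test_that("raster text serialization round-trips", {
  net <- smallTestNetwork()
  dr <- driveParams(etaBkgE = 420, etaBkgI = 420, sDriveE = 0.6,
                    sDriveI = 0.5)
  res <- runSimulation(net, dr, NULL, simConfig(duration = 500, seed = 8))
  f <- file.path(tempdir(), "raster.tsv")
  writeSpikeRaster(raster(res), f)
  r2 <- readSpikeRaster(f)
  expect_identical(spikes(r2), spikes(res))
  expect_identical(r2@duration, 500)
})
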