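# Cross-covariance and spike-triggered voltage distributions.

mkRaster <- function(sp, duration, geom) {
  sp <- sp[order(sp$t), ]
  rownames(sp) <- NULL
  new("SpikeRaster", spikes = sp, duration = duration, geometry = geom,
      seed = NA_real_)
}

test_that("an empty raster gives an identically zero cross-covariance", {
  g <- networkGeometry(2, 2, 2, 2)
  r <- mkRaster(data.frame(t = numeric(0), Q = character(0), j = integer(0),
                           k = integer(0), l = integer(0), id = integer(0),
                           instant = integer(0)), 1000, g)
  x <- crossCovariance(r, "E", "E", A = 1, B = 0, tauMax = 50)
  expect_true(all(x@raw == 0))
  expect_true(all(x@meanSub == 0))
})

test_that("two single spikes offset by Delta light up only tau = +-Delta", {
  g <- networkGeometry(2, 1, 2, 2)   # two hypercolumns, one orientation
  # neuron 1 (E, k=1) spikes at 100; neuron id for (k=2, E, l=1) is 5
  sp <- data.frame(t = c(100, 107), Q = "E", j = 1L, k = c(1L, 2L),
                   l = 1L, id = c(1L, 5L), instant = NA_integer_)
  r <- mkRaster(sp, 1000, g)
  x <- crossCovariance(r, "E", "E", A = 1, B = 0, tauMax = 20, dt = 1)
  hot <- which(x@raw != 0)
  expect_setequal(x@tau[hot], c(-7, 7))
  expect_equal(x@raw[hot], c(1, 1))
})

test_that("same-population classes give symmetric raw cross-covariance", {
  pr <- makePlantedRaster(plantedRasterSpec(nE = 10, nI = 10, nullRate = 25,
                                            duration = 2000, seed = 31))
  # reshape onto a 2-hypercolumn geometry so B = 0 classes exist
  g2 <- networkGeometry(2, 1, 5, 5)
  sp <- spikes(pr$raster)
  nt <- MFEsim:::makeNeuronTable(g2)
  sp$id <- ((sp$id - 1L) %% 20L) + 1L
  sp$Q <- nt$type[sp$id]; sp$j <- nt$j[sp$id]; sp$k <- nt$k[sp$id]
  sp$l <- nt$l[sp$id]
  r <- mkRaster(sp, 2000, g2)
  for (AB in list(c(1, 1), c(1, 0))) {
    x <- crossCovariance(r, "E", "E", A = AB[1], B = AB[2], tauMax = 30)
    expect_equal(x@raw, rev(x@raw))
    expect_equal(x@meanSub, rev(x@meanSub))
  }
})

test_that("the estimator equals the direct double-loop oracle bit-exactly", {
  # 10 neurons over a 2x1 geometry, 1 s raster
  g <- networkGeometry(2, 1, 3, 2)
  pr <- makePlantedRaster(plantedRasterSpec(nE = 6, nI = 4, nullRate = 40,
                                            duration = 1000, seed = 17))
  sp <- spikes(pr$raster)
  nt <- MFEsim:::makeNeuronTable(g)
  sp$id <- ((sp$id - 1L) %% 10L) + 1L
  sp$Q <- nt$type[sp$id]; sp$j <- nt$j[sp$id]; sp$k <- nt$k[sp$id]
  sp$l <- nt$l[sp$id]
  r <- mkRaster(sp, 1000, g)
  for (Q in c("E", "I")) for (A in 1) for (B in c(1, 0)) {
    x <- crossCovariance(r, Q, Q, A = A, B = B, tauMax = 100, dt = 1)
    o <- xcovDoubleLoop(r, Q, Q, A = A, B = B, tauMax = 100, dt = 1)
    expect_identical(x@raw, o$raw)
    expect_equal(x@meanSub, o$meanSub, tolerance = 1e-12)
  }
  xEI <- crossCovariance(r, "E", "I", A = 1, B = 0, tauMax = 100, dt = 1)
  oEI <- xcovDoubleLoop(r, "E", "I", A = 1, B = 0, tauMax = 100, dt = 1)
  expect_identical(xEI@raw, oEI$raw)
})

test_that("independent Poisson populations have flat mean-subtracted C", {
  g <- networkGeometry(2, 1, 32, 1)
  pr <- makePlantedRaster(plantedRasterSpec(nE = 64, nI = 2, nullRate = 15,
                                            duration = 8000, seed = 23))
  sp <- spikes(pr$raster)
  nt <- MFEsim:::makeNeuronTable(g)
  sp$id <- ((sp$id - 1L) %% 66L) + 1L
  sp$Q <- nt$type[sp$id]; sp$j <- nt$j[sp$id]; sp$k <- nt$k[sp$id]
  sp$l <- nt$l[sp$id]
  r <- mkRaster(sp, 8000, g)
  x <- crossCovariance(r, "E", "E", A = 1, B = 0, tauMax = 100, dt = 1)
  # null scale: each lag sums nPairs * T products of independent centered
  # Bernoulli(p) values, so sd = sqrt(nPairs * T) * p (1 - p)
  nPairs <- x@meta$nPairs
  p <- 15 / 1000
  sdNull <- sqrt(nPairs * x@meta$T) * p * (1 - p)
  expect_lt(max(abs(x@meanSub)), 4 * sdNull)
})

test_that("a geometry without the requested pair class errors by name", {
  g <- networkGeometry(1, 1, 4, 4)
  pr <- makePlantedRaster(plantedRasterSpec(nE = 4, nI = 4, nullRate = 10,
                                            duration = 500, seed = 2))
  expect_error(crossCovariance(pr$raster, "E", "E", A = 1, B = 0),
               "class")
})

test_that("spike-triggered voltage picks out planted structure", {
  g <- networkGeometry(2, 1, 2, 2)
  tt <- seq(0, 400, by = 1)
  nV <- 8
  fullV <- matrix(0.2, length(tt), 8)
  fullV[, 5] <- 0.8   # same-orientation partner in the other hypercolumn
  cm <- matrix(0.3, length(tt), 4,
               dimnames = list(NULL, c("E.1.1", "I.1.1", "E.1.2", "I.1.2")))
  vt <- new("VoltageTrace", time = tt, clusterV = cm, fullV = fullV,
            geometry = g)
  sp <- data.frame(t = c(200, 250), Q = "E", j = 1L, k = 1L, l = 1L,
                   id = 1L, instant = NA_integer_)
  r <- mkRaster(sp, 400, g)
  stv <- spikeTriggeredVoltage(r, vt, Q = "E", Qp = "E", A = 1, B = 0,
                               tauGrid = c(-10, 0, 10), burnIn = 0)
  # partners are neurons 5 and 6 (E in k=2): voltages 0.8 and 0.2
  expect_identical(stv@nTriggers, 2L)
  expect_equal(stv@mean, rep(0.5, 3))
  # one trigger, one target held at a constant: point mass there
  spi <- mkRaster(sp[1, ], 400, g)
  stv1 <- spikeTriggeredVoltage(spi, vt, Q = "E", Qp = "I", A = 1, B = 0,
                                tauGrid = 0, burnIn = 0)
  expect_equal(stv1@mean, 0.2)
  expect_equal(sum(stv1@density[, 1] > 0), 1L)
  # no triggers: empty result
  stv0 <- spikeTriggeredVoltage(mkRaster(sp[0, ], 400, g), vt,
                                tauGrid = 0, burnIn = 0)
  expect_identical(stv0@nTriggers, 0L)
  # missing coverage errors unless trimming is requested
  expect_error(spikeTriggeredVoltage(r, vt, tauGrid = c(-180), burnIn = 0),
               "missing")
  stvT <- spikeTriggeredVoltage(r, vt, tauGrid = c(-180), burnIn = 0,
                                trim = TRUE)   # only the t = 200 trigger is covered
  expect_identical(stvT@nTriggers, 1L)
})
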