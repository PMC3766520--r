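# Scripted benchmark protocols and synthetic fixture generators.

#' Specify a synthetic raster with planted synchronous events
#'
#' @param nE,nI population sizes
#' @param nullRate homogeneous Poisson rate per neuron, Hz
#' @param duration ms
#' @param events data.frame with columns \code{t}, \code{sizeE},
#'   \code{sizeI} (or empty for a pure Poisson raster)
#' @param seed RNG seed
#' @return a validated \linkS4class{PlantedRasterSpec}
#' @export
plantedRasterSpec <- function(nE = 128, nI = 128, nullRate = 3,
                              duration = 10000,
                              events = data.frame(t = numeric(0),
                                                  sizeE = integer(0),
                                                  sizeI = integer(0)),
                              seed = 1) {
  new("PlantedRasterSpec", nE = as.integer(nE), nI = as.integer(nI),
      nullRate = nullRate, duration = duration, events = events,
      seed = seed)
}

#' Generate a homogeneous Poisson raster with planted synchronous events
#'
#' Emulates the null model behind the 95 % rule -- every neuron an
#' independent homogeneous Poisson process -- with optional synchronous
#' events of known times and sizes injected on top, for testing the MFE
#' detector without the simulator.
#'
#' @param spec a \linkS4class{PlantedRasterSpec}
#' @return list with \code{raster} (a \linkS4class{SpikeRaster} over a
#'   1-hypercolumn, 1-orientation geometry) and \code{truth} (the planted
#'   event table)
#' @export
makePlantedRaster <- function(spec) {
  validObject(spec)
  g <- networkGeometry(1, 1, max(spec@nE, 1L), max(spec@nI, 1L))
  lam <- spec@nullRate / 1000
  withSeed(spec@seed, {
    tL <- list(); idL <- list(); qL <- list()
    for (pop in c("E", "I")) {
      nPop <- if (pop == "E") spec@nE else spec@nI
      if (nPop == 0) next
      counts <- if (lam > 0) stats::rpois(nPop, lam * spec@duration)
                else integer(nPop)
      for (i in seq_len(nPop)) {
        if (counts[i] > 0) {
          tL[[length(tL) + 1L]] <- runif(counts[i], 0, spec@duration)
          idL[[length(idL) + 1L]] <- rep(i, counts[i])
          qL[[length(qL) + 1L]] <- rep(pop, counts[i])
        }
      }
      ev <- spec@events
      sizeCol <- if (pop == "E") "sizeE" else "sizeI"
      for (z in seq_len(nrow(ev))) {
        sz <- ev[[sizeCol]][z]
        if (sz > 0) {
          who <- sample.int(nPop, sz)
          tL[[length(tL) + 1L]] <- rep(ev$t[z], sz)
          idL[[length(idL) + 1L]] <- who
          qL[[length(qL) + 1L]] <- rep(pop, sz)
        }
      }
    }
    tv <- unlist(tL); idv <- unlist(idL); qv <- unlist(qL)
    if (is.null(tv)) { tv <- numeric(0); idv <- integer(0); qv <- character(0) }
    o <- order(tv)
    gid <- ifelse(qv == "E", idv, spec@nE + idv)
    one <- rep(1L, length(tv))
    sp <- data.frame(t = tv[o], Q = qv[o], j = one, k = one, l = idv[o],
                     id = gid[o], instant = rep(NA_integer_, length(tv)))
    list(raster = new("SpikeRaster", spikes = sp, duration = spec@duration,
                      geometry = g, seed = spec@seed),
         truth = spec@events)
  })
}

#' Background activity protocol
#'
#' Runs the regime with background drive only and computes the statistics
#' of spontaneous correlated activity: per-orientation activity episodes
#' (persistence timescale), and the cross-covariance of E spiking with E
#' and I populations across hypercolumns for matching (A=1) and
#' non-matching (A=0) orientations.
#'
#' @param regime a \linkS4class{Regime}
#' @param duration run length, ms (>= 8000 recommended)
#' @param seed master seed
#' @param tauMax cross-covariance lag range, ms
#' @param burnIn ms excluded from analysis
#' @param stv also compute spike-triggered voltage panels (needs full
#'   voltage sampling; memory-heavy)
#' @param sampleInterval voltage sampling interval, ms
#' @return list: \code{result} (\linkS4class{SimResult}), \code{episodes},
#'   \code{tauPersist}, \code{xcov} (list over Q' and A), \code{rates}
#'   (background E/I rates in Hz), optionally \code{stv}
#' @export
backgroundProtocol <- function(regime, duration = 8000, seed = 1,
                               tauMax = 400, burnIn = 500, stv = FALSE,
                               sampleInterval = 1) {
  net <- regimeNetwork(regime, seed = seed)
  cfg <- simConfig(duration = duration, seed = seed + 1,
                   sampleInterval = sampleInterval,
                   sampleMode = if (stv) "full" else "cluster")
  res <- runSimulation(net, regime@drive, NULL, cfg,
                       params = regime@neuron, kernels = regime@kernels)
  ep <- backgroundEpisodes(res, burnIn = burnIn)
  xcov <- list()
  if (regime@geometry@nHypercolumns > 1) {
    for (Qp in c("E", "I")) for (A in c(1, 0)) {
      xcov[[sprintf("C.E.%s.A%d.B0", Qp, A)]] <-
        crossCovariance(res, "E", Qp, A = A, B = 0, tauMax = tauMax,
                        burnIn = burnIn)
    }
  }
  sp <- spikes(res)
  live <- sp$t >= burnIn
  g <- regime@geometry
  nE <- g@nE * nClusters(g); nI <- g@nI * nClusters(g)
  rates <- c(E = sum(live & sp$Q == "E") / nE / (duration - burnIn) * 1000,
             I = sum(live & sp$Q == "I") / nI / (duration - burnIn) * 1000)
  out <- list(result = res, episodes = ep$episodes,
              tauPersist = ep$tauPersist, xcov = xcov, rates = rates)
  if (stv) {
    out$stv <- list(
      sameTheta = spikeTriggeredVoltage(res, Q = "E", Qp = "E", A = 1,
                                        B = 0, burnIn = burnIn, trim = TRUE),
      diffTheta = spikeTriggeredVoltage(res, Q = "E", Qp = "E", A = 0,
                                        B = 0, burnIn = burnIn, trim = TRUE))
  }
  out
}

#' Iso-oriented surround suppression protocol
#'
#' For each stimulus size n, stimulates n same-orientation clusters (the
#' center plus n-1 other hypercolumns) and reports the center cluster's
#' steady-state rates with the I-population MFE decomposition.
#'
#' @param regime a \linkS4class{Regime}
#' @param contrast excitatory contrast of the stimulus
#' @param nStim vector of stimulus sizes (numbers of stimulated clusters,
#'   each in 1..nHypercolumns)
#' @param duration run length, ms
#' @param seed master seed (the network build is shared across conditions)
#' @param center (j, k) of the center cluster
#' @param onset stimulus onset, ms; rates are computed from
#'   \code{onset + settle} onward
#' @param settle post-onset exclusion for steady-state rates, ms
#' @param phaseFree use the phase-free constant-rate stimulus variant
#' @return list: \code{rates} (data.frame from \code{\link{rateCurves}}),
#'   \code{runs} (list of \linkS4class{SimResult})
#' @export
surroundSuppressionProtocol <- function(regime, contrast = 0.75,
                                        nStim = c(1, 8), duration = 6000,
                                        seed = 1, center = c(1, 1),
                                        onset = 0, settle = 500,
                                        phaseFree = TRUE) {
  K <- regime@geometry@nHypercolumns
  if (any(nStim < 1 | nStim > K)) stop("nStim values must lie in 1..K")
  net <- regimeNetwork(regime, seed = seed)
  runs <- list()
  for (z in seq_along(nStim)) {
    n <- nStim[z]
    ks <- c(center[2], setdiff(seq_len(K), center[2]))[seq_len(n)]
    stim <- stimulusSpec(j = center[1], k = ks, contrastE = contrast,
                         phaseFree = phaseFree, onset = onset)
    cfg <- simConfig(duration = duration, seed = seed + 100 + z,
                     sampleInterval = 1, sampleMode = "cluster")
    runs[[as.character(n)]] <-
      runSimulation(net, regime@drive, stim, cfg,
                    params = regime@neuron, kernels = regime@kernels)
  }
  rates <- rateCurves(runs, cluster = center, burnIn = onset + settle)
  list(rates = rates, runs = runs)
}

#' Contrast x stimulus-size sweep of excitatory firing
#'
#' Time-averaged E rate in the center cluster over a grid of contrasts and
#' stimulus sizes (numbers of stimulated same-orientation clusters).
#'
#' @param regime a \linkS4class{Regime}
#' @param contrasts contrast grid (defaults to the four standard values
#'   0.75, 0.375, 0.1875, 0.0938)
#' @param nStim stimulus-size grid
#' @param duration per-condition run length, ms
#' @param seed master seed
#' @param center,onset,settle,phaseFree as in
#'   \code{\link{surroundSuppressionProtocol}}
#' @return list: \code{rateE} (matrix contrasts x sizes),
#'   \code{contrasts}, \code{nStim}
#' @export
contrastSizeSweep <- function(regime,
                              contrasts = c(0.7500, 0.3750, 0.1875, 0.0938),
                              nStim = c(1, 2, 4, 8), duration = 4000,
                              seed = 1, center = c(1, 1), onset = 0,
                              settle = 500, phaseFree = TRUE) {
  stopifnot(all(contrasts > 0))
  rateE <- matrix(NA_real_, length(contrasts), length(nStim),
                  dimnames = list(sprintf("%.4f", contrasts),
                                  as.character(nStim)))
  for (ci in seq_along(contrasts)) {
    ss <- surroundSuppressionProtocol(regime, contrast = contrasts[ci],
                                      nStim = nStim, duration = duration,
                                      seed = seed + 1000 * ci,
                                      center = center, onset = onset,
                                      settle = settle,
                                      phaseFree = phaseFree)
    rateE[ci, ] <- ss$rates$rateE
  }
  list(rateE = rateE, contrasts = contrasts, nStim = nStim)
}

#' Recompute a regime's qualitative benchmark checklist
#'
#' Re-runs scaled-down versions of the benchmark protocols and reports the
#' qualitative statuses stored with the regime: plausible background rates,
#' background-pattern persistence within 50--500 ms, surround suppression
#' of center E firing (>= 20 % relative drop, the package's convention for
#' "significant"), gamma-band elevation of the LFP proxy under drive, and a
#' trial-to-trial CV drop after stimulus onset.
#'
#' @param regime a \linkS4class{Regime}
#' @param seed master seed
#' @param bgDuration,ssDuration,cvTrials,cvDuration problem sizes of the
#'   re-runs
#' @return named logical vector mirroring \code{regime@checklist}
#' @export
regimeChecklist <- function(regime, seed = 1, bgDuration = 12000,
                            ssDuration = 4000, cvTrials = 6,
                            cvDuration = 3000) {
  bg <- backgroundProtocol(regime, duration = bgDuration, seed = seed,
                           tauMax = 100)
  ss <- surroundSuppressionProtocol(regime, nStim = c(1, 8),
                                    duration = ssDuration, seed = seed)
  # gamma-band comparison: background vs the driven center cluster
  psdBg <- lfpPSD(voltageTrace(bg$result))
  psdDr <- lfpPSD(voltageTrace(ss$runs[["1"]]))
  # trial CV pre vs post onset in the driven cluster
  net <- regimeNetwork(regime, seed = seed)
  onset <- cvDuration / 2
  stim <- stimulusSpec(j = 1, k = 1, contrastE = 0.75, phaseFree = TRUE,
                       onset = onset)
  cfg <- simConfig(duration = cvDuration, seed = seed)
  trials <- runTrials(net, regime@drive, stim, cfg,
                      seeds = seed + seq_len(cvTrials) * 17,
                      params = regime@neuron, kernels = regime@kernels)
  cvPre <- trialCV(trials, window = c(onset - 1000, onset),
                   population = "E", cluster = c(1, 1))
  cvPost <- trialCV(trials, window = c(onset + 100, onset + 1100),
                    population = "E", cluster = c(1, 1))
  rE1 <- ss$rates$rateE[ss$rates$condition == "1"]
  rE8 <- ss$rates$rateE[ss$rates$condition == "8"]
  c(background_rates_plausible =
      unname(bg$rates["E"] >= 0.5 && bg$rates["E"] <= 15 &&
             bg$rates["I"] >= 1 && bg$rates["I"] <= 30),
    episodes_50_500ms =
      is.finite(bg$tauPersist) && bg$tauPersist >= 50 &&
      bg$tauPersist <= 500,
    surround_suppression_E = rE8 < 0.8 * rE1,
    gamma_elevated_under_drive = bandPower(psdDr) > bandPower(psdBg),
    cv_drop_at_onset = cvPost$median < cvPre$median)
}
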