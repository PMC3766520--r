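# The hybrid event-driven / substep simulation loop.

# flatten a network's edges into the CSC-by-sender arrays the C++ engine uses
engineEdges <- function(network) {
  Wf <- network@Wfast; Ws <- network@Wslow
  tf <- Matrix::summary(Wf); ts <- Matrix::summary(Ws)
  stopifnot(identical(tf$i, ts$i), identical(tf$j, ts$j))
  nt <- network@neurons
  list(ptr = Wf@p, rcv = Wf@i, wf = Wf@x, ws = Ws@x,
       lr = nt$k[tf$j] != nt$k[tf$i])
}

#' Run one network simulation
#'
#' Advances the whole network: neurons relax between events under leak and
#' their decaying slow conductance (exponential substeps); feedforward
#' Poisson arrivals are instantaneous fast-E jumps at their exact times; any
#' threshold crossing triggers exact cascade resolution over the network at
#' that instant (or, with finite fast kernels, an ordinary conductance
#' delivery).  All randomness -- initial voltages, every neuron's input
#' train, cascade tie-breaks, stimulus phases -- derives from the master
#' seed, so a run is bit-reproducible given its configuration.
#'
#' Initial voltages are uniform in [Vreset, 0.95 VT] to avoid startup
#' synchrony; analyses discard a burn-in (500 ms by default) on top of that.
#'
#' @param network a \linkS4class{CortexNetwork}
#' @param drive a \linkS4class{DriveParams}
#' @param stimulus a \linkS4class{StimulusSpec} or NULL for background only
#' @param config a \linkS4class{SimConfig}
#' @param params a \linkS4class{NeuronParams}
#' @param kernels a \linkS4class{SynapticKernels}; equal fast decay times
#'   are required (the model takes them comparable), 0 = instantaneous limit
#' @param maxMeanRate abort (with a diagnostic) if the network-mean firing
#'   rate exceeds this many Hz/neuron -- a runaway-regime guard
#' @return a \linkS4class{SimResult}
#' @export
runSimulation <- function(network, drive, stimulus = NULL, config,
                          params = neuronParams(),
                          kernels = synapticKernels(),
                          maxMeanRate = Inf) {
  validObject(config); validObject(params); validObject(kernels)
  if (kernels@tauFastE != kernels@tauFastI)
    stop("the engine requires tauFastE == tauFastI (the model takes the ",
         "fast timescales comparable as both go to zero)")
  nt <- network@neurons
  n <- nrow(nt)
  ed <- engineEdges(network)

  etaBkg <- ifelse(nt$type == "E", drive@etaBkgE, drive@etaBkgI)
  sDrive <- ifelse(nt$type == "E", drive@sDriveE, drive@sDriveI)
  contrast <- numeric(n)
  phase <- numeric(n)
  omega <- 4; phaseFree <- TRUE; onset <- 0
  if (!is.null(stimulus) && nrow(stimulus@targets)) {
    validObject(stimulus)
    omega <- stimulus@omega
    phaseFree <- stimulus@phaseFree
    onset <- stimulus@onset
    tg <- stimulus@targets
    for (r in seq_len(nrow(tg))) {
      inCl <- nt$j == tg$j[r] & nt$k == tg$k[r]
      contrast[inCl & nt$type == "E"] <- tg$contrastE[r]
      contrast[inCl & nt$type == "I"] <- tg$contrastI[r]
    }
    if (!phaseFree) {
      period <- 1000 / omega
      phase <- withSeed(config@seed + 7, runif(n, 0, period))
    }
  }

  delay <- if (is.na(config@delay)) network@connectivity@delay else config@delay
  sampleInterval <- if (config@sampleMode == "none") 0 else config@sampleInterval
  sampleMode <- match(config@sampleMode, c("none", "cluster", "full")) - 1L

  res <- cpp_run_engine(
    type = as.integer(nt$type == "I"), clust = nt$cluster - 1L,
    nClust = nClusters(network),
    e_ptr = ed$ptr, e_rcv = ed$rcv, e_wf = ed$wf, e_ws = ed$ws,
    e_lr = ed$lr,
    etaBkgHz = etaBkg, contrast = contrast, phase_ms = phase,
    omegaHz = omega, phaseFree = phaseFree, onset_ms = onset,
    sDrive = sDrive,
    par = list(VL = params@VL, VE = params@VE, VI = params@VI,
               VT = params@VT, Vreset = params@Vreset, tauV = params@tauV,
               tauRef = params@tauRef, tauSlow = kernels@tauSlow,
               tauFast = kernels@tauFastE),
    duration = config@duration, substep = config@substep,
    sampleInterval = sampleInterval, sampleMode = sampleMode,
    delay_ms = delay, seed = config@seed,
    maxSpikes = if (is.finite(maxMeanRate))
      maxMeanRate * n * config@duration / 1000 else Inf)

  id <- res$spike_id + 1L
  sp <- data.frame(t = res$spike_t, Q = nt$type[id], j = nt$j[id],
                   k = nt$k[id], l = nt$l[id], id = id,
                   instant = res$spike_instant)
  rast <- new("SpikeRaster", spikes = sp, duration = config@duration,
              geometry = network@geometry, seed = config@seed)

  vt <- NULL
  if (sampleMode > 0L) {
    nC <- nClusters(network)
    cm <- matrix(res$cluster_V, nrow = length(res$sample_t), ncol = nC * 2,
                 byrow = TRUE)
    cj <- (seq_len(nC) - 1L) %% network@geometry@nOrientations + 1L
    ck <- (seq_len(nC) - 1L) %/% network@geometry@nOrientations + 1L
    cn <- character(nC * 2)
    cn[2 * seq_len(nC) - 1L] <- sprintf("E.%d.%d", cj, ck)
    cn[2 * seq_len(nC)] <- sprintf("I.%d.%d", cj, ck)
    colnames(cm) <- cn
    fv <- NULL
    if (sampleMode == 2L)
      fv <- matrix(res$full_V, nrow = length(res$sample_t), ncol = n,
                   byrow = TRUE)
    vt <- new("VoltageTrace", time = res$sample_t, clusterV = cm,
              fullV = fv, geometry = network@geometry)
  }

  man <- list(
    package_version = as.character(utils::packageVersion("MFEsim")),
    seed = config@seed, duration = config@duration,
    substep = config@substep, sampleInterval = sampleInterval,
    sampleMode = config@sampleMode, delay = delay,
    burn_in_note = "initial voltages uniform in [Vreset, 0.95 VT]; analyses discard a configurable burn-in (default 500 ms)",
    geometry = list(nHypercolumns = network@geometry@nHypercolumns,
                    nOrientations = network@geometry@nOrientations,
                    nE = network@geometry@nE, nI = network@geometry@nI),
    network_seed = network@seed,
    drive = list(etaBkgE = drive@etaBkgE, etaBkgI = drive@etaBkgI,
                 sDriveE = drive@sDriveE, sDriveI = drive@sDriveI),
    stimulus = if (is.null(stimulus) || !nrow(stimulus@targets)) NULL else
      list(targets = stimulus@targets, omega = stimulus@omega,
           phaseFree = stimulus@phaseFree, onset = stimulus@onset),
    neuron = list(VL = params@VL, VE = params@VE, VI = params@VI,
                  VT = params@VT, Vreset = params@Vreset,
                  tauV = params@tauV, tauRef = params@tauRef),
    kernels = list(tauSlow = kernels@tauSlow, tauFastE = kernels@tauFastE,
                   tauFastI = kernels@tauFastI),
    n_instants = res$n_instants)

  new("SimResult", raster = rast, voltage = vt, manifest = man)
}

#' Run repeated trials of one configuration
#'
#' Identical network and stimulus, independent seeds.  Outputs share the
#' stimulus-onset time, so post-onset windows are aligned across trials.
#'
#' @param network,drive,stimulus,config,params,kernels as in
#'   \code{\link{runSimulation}}
#' @param seeds vector of per-trial master seeds (duplicates warn)
#' @return list of \linkS4class{SimResult}
#' @export
runTrials <- function(network, drive, stimulus = NULL, config, seeds,
                      params = neuronParams(), kernels = synapticKernels()) {
  stopifnot(length(seeds) >= 1)
  if (anyDuplicated(seeds))
    warning("duplicate seeds: trials will not be independent")
  lapply(seeds, function(s) {
    cfg <- config
    cfg@seed <- s
    runSimulation(network, drive, stimulus, cfg, params, kernels)
  })
}

#' Write / read a spike raster as columnar text
#'
#' Header lines (\code{#key: value}) carry the metadata; the body is
#' tab-separated \code{t_ms Q j k l id instant}.
#'
#' @param x a \linkS4class{SpikeRaster}
#' @param file path
#' @return \code{writeSpikeRaster}: the path, invisibly;
#'   \code{readSpikeRaster}: the reconstructed raster
#' @export
writeSpikeRaster <- function(x, file) {
  g <- x@geometry
  hdr <- c(sprintf("#duration_ms: %.17g", x@duration),
           sprintf("#seed: %.17g", x@seed),
           sprintf("#geometry: %d %d %d %d", g@nHypercolumns,
                   g@nOrientations, g@nE, g@nI),
           "#columns: t_ms Q j k l id instant")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  sp <- x@spikes
  inst <- if ("instant" %in% names(sp)) sp$instant else NA_integer_
  body <- sprintf("%.17g\t%s\t%d\t%d\t%d\t%d\t%s", sp$t, sp$Q, sp$j, sp$k,
                  sp$l, sp$id, ifelse(is.na(inst), "NA", as.character(inst)))
  writeLines(body, con)
  invisible(file)
}

#' @rdname writeSpikeRaster
#' @export
readSpikeRaster <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) sub(paste0("#", key, ": "), "",
                            hdr[startsWith(hdr, paste0("#", key, ":"))])
  gg <- as.integer(strsplit(getv("geometry"), " ")[[1]])
  body <- lines[!startsWith(lines, "#")]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    m <- do.call(rbind, parts)
    sp <- data.frame(t = as.numeric(m[, 1]), Q = m[, 2],
                     j = as.integer(m[, 3]), k = as.integer(m[, 4]),
                     l = as.integer(m[, 5]), id = as.integer(m[, 6]),
                     instant = suppressWarnings(as.integer(m[, 7])))
  } else {
    sp <- data.frame(t = numeric(0), Q = character(0), j = integer(0),
                     k = integer(0), l = integer(0), id = integer(0),
                     instant = integer(0))
  }
  new("SpikeRaster", spikes = sp, duration = as.numeric(getv("duration_ms")),
      geometry = networkGeometry(gg[1], gg[2], gg[3], gg[4]),
      seed = as.numeric(getv("seed")))
}
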