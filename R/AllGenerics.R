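# Constructors, accessors and show methods.

#' @rdname NeuronParams-class
#' @param VL,VE,VI,VT,Vreset,tauV,tauRef see the class slots
#' @return a validated \linkS4class{NeuronParams}
#' @examples
#' neuronParams()
#' @export
neuronParams <- function(VL = 0, VE = 14 / 3, VI = -2 / 3, VT = 1,
                         Vreset = 0, tauV = 20, tauRef = 1) {
  new("NeuronParams", VL = VL, VE = VE, VI = VI, VT = VT, Vreset = Vreset,
      tauV = tauV, tauRef = tauRef)
}

#' @rdname SynapticKernels-class
#' @param tauSlow,tauFastE,tauFastI see the class slots
#' @export
synapticKernels <- function(tauSlow = 128, tauFastE = 0, tauFastI = 0) {
  new("SynapticKernels", tauSlow = tauSlow, tauFastE = tauFastE,
      tauFastI = tauFastI)
}

#' @rdname NeuronState-class
#' @param V,gSlow,refractoryUntil,pop see the class slots; scalars recycled
#' @export
neuronState <- function(V, gSlow = 0, refractoryUntil = -Inf, pop = "E") {
  n <- length(V)
  new("NeuronState", V = as.numeric(V),
      gSlow = rep_len(as.numeric(gSlow), n),
      refractoryUntil = rep_len(as.numeric(refractoryUntil), n),
      pop = rep_len(pop, n))
}

#' @rdname NetworkGeometry-class
#' @param nHypercolumns,nOrientations,nE,nI see the class slots
#' @export
networkGeometry <- function(nHypercolumns = 8, nOrientations = 3,
                            nE = 128, nI = 128) {
  new("NetworkGeometry", nHypercolumns = as.integer(nHypercolumns),
      nOrientations = as.integer(nOrientations),
      nE = as.integer(nE), nI = as.integer(nI))
}

#' @rdname DriveParams-class
#' @param etaBkgE,etaBkgI,sDriveE,sDriveI see the class slots
#' @export
driveParams <- function(etaBkgE = 375, etaBkgI = 375,
                        sDriveE = 0.05, sDriveI = 0.05) {
  new("DriveParams", etaBkgE = etaBkgE, etaBkgI = etaBkgI,
      sDriveE = sDriveE, sDriveI = sDriveI)
}

#' @rdname SimConfig-class
#' @param duration,sampleInterval,sampleMode,seed,substep,delay see the slots
#' @export
simConfig <- function(duration, seed = 1, sampleInterval = 0,
                      sampleMode = c("none", "cluster", "full"),
                      substep = 0.1, delay = NA_real_) {
  sampleMode <- match.arg(sampleMode)
  if (sampleMode != "none" && sampleInterval <= 0) sampleInterval <- 1
  new("SimConfig", duration = duration, sampleInterval = sampleInterval,
      sampleMode = sampleMode, seed = seed, substep = substep, delay = delay)
}

# ---- generics -------------------------------------------------------------

#' Number of neurons described by an object
#' @param x an object with a notion of population size
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' Number of clusters (orientation domains)
#' @param x an object with network geometry
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Network geometry of an object
#' @param x an object carrying a \linkS4class{NetworkGeometry}
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Fast-synaptic weight matrix (receiver x sender)
#' @param x a \linkS4class{CortexNetwork}
#' @export
setGeneric("fastWeights", function(x) standardGeneric("fastWeights"))

#' Slow-synaptic weight matrix (receiver x sender)
#' @param x a \linkS4class{CortexNetwork}
#' @export
setGeneric("slowWeights", function(x) standardGeneric("slowWeights"))

#' Neuron table of a network
#' @param x a \linkS4class{CortexNetwork}
#' @export
setGeneric("neuronTable", function(x) standardGeneric("neuronTable"))

#' Spike records of a raster or simulation result
#' @param x a \linkS4class{SpikeRaster} or \linkS4class{SimResult}
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))

#' Number of spikes
#' @param x a \linkS4class{SpikeRaster} or \linkS4class{SimResult}
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' Spike raster of a simulation result
#' @param x a \linkS4class{SimResult}
#' @export
setGeneric("raster", function(x) standardGeneric("raster"))

#' Voltage trace of a simulation result
#' @param x a \linkS4class{SimResult}
#' @export
setGeneric("voltageTrace", function(x) standardGeneric("voltageTrace"))

#' Run manifest of a simulation result
#' @param x a \linkS4class{SimResult}
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' Total cascade magnitude
#' @param x a \linkS4class{CascadeResult}
#' @export
setGeneric("magnitude", function(x) standardGeneric("magnitude"))

# ---- methods --------------------------------------------------------------

#' @rdname nClusters
#' @export
setMethod("nClusters", "NetworkGeometry", function(x)
  x@nHypercolumns * x@nOrientations)

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "NetworkGeometry", function(x)
  nClusters(x) * (x@nE + x@nI))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "CortexNetwork", function(x) nrow(x@neurons))

#' @rdname nClusters
#' @export
setMethod("nClusters", "CortexNetwork", function(x) nClusters(x@geometry))

#' @rdname geometry
#' @export
setMethod("geometry", "CortexNetwork", function(x) x@geometry)

#' @rdname geometry
#' @export
setMethod("geometry", "SpikeRaster", function(x) x@geometry)

#' @rdname fastWeights
#' @export
setMethod("fastWeights", "CortexNetwork", function(x) x@Wfast)

#' @rdname slowWeights
#' @export
setMethod("slowWeights", "CortexNetwork", function(x) x@Wslow)

#' @rdname neuronTable
#' @export
setMethod("neuronTable", "CortexNetwork", function(x) x@neurons)

#' @rdname spikes
#' @export
setMethod("spikes", "SpikeRaster", function(x) x@spikes)

#' @rdname spikes
#' @export
setMethod("spikes", "SimResult", function(x) x@raster@spikes)

#' @rdname nSpikes
#' @export
setMethod("nSpikes", "SpikeRaster", function(x) nrow(x@spikes))

#' @rdname nSpikes
#' @export
setMethod("nSpikes", "SimResult", function(x) nrow(x@raster@spikes))

#' @rdname raster
#' @export
setMethod("raster", "SimResult", function(x) x@raster)

#' @rdname voltageTrace
#' @export
setMethod("voltageTrace", "SimResult", function(x) x@voltage)

#' @rdname manifest
#' @export
setMethod("manifest", "SimResult", function(x) x@manifest)

#' @rdname magnitude
#' @export
setMethod("magnitude", "CascadeResult", function(x)
  length(x@firedE) + length(x@firedI))

setMethod("show", "NetworkGeometry", function(object) {
  cat(sprintf("NetworkGeometry: %d hypercolumns x %d orientations = %d clusters, N_E=%d N_I=%d per cluster (%d neurons)\n",
              object@nHypercolumns, object@nOrientations, nClusters(object),
              object@nE, object@nI, nNeurons(object)))
})

setMethod("show", "CortexNetwork", function(object) {
  cat("CortexNetwork\n")
  show(object@geometry)
  cat(sprintf("  edges: %d (fast), %d nonzero slow; build seed %s\n",
              length(object@Wfast@x), sum(object@Wslow@x > 0),
              format(object@seed)))
})

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf("SpikeRaster: %d spikes over %.1f ms", nrow(object@spikes),
              object@duration))
  if (nrow(object@spikes))
    cat(sprintf(" (mean rate %.2f Hz/neuron)",
                nrow(object@spikes) / nNeurons(object@geometry) /
                  object@duration * 1000))
  cat("\n")
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult: magnitude %d (%d E + %d I)\n",
              magnitude(object), length(object@firedE),
              length(object@firedI)))
})

setMethod("show", "SimResult", function(object) {
  cat("SimResult\n  ")
  show(object@raster)
  if (is(object@voltage, "VoltageTrace") && length(object@voltage@time))
    cat(sprintf("  voltage: %d samples x %d populations\n",
                length(object@voltage@time), ncol(object@voltage@clusterV)))
})

setMethod("show", "Regime", function(object) {
  cat(sprintf("Regime '%s'\n", object@name))
  show(object@geometry)
  cat(sprintf("  drive: eta_bkg E/I %.0f/%.0f Hz, S_drive E/I %.4f/%.4f\n",
              object@drive@etaBkgE, object@drive@etaBkgI,
              object@drive@sDriveE, object@drive@sDriveI))
  if (length(object@notes)) cat("  notes:", object@notes[1], "\n")
})
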