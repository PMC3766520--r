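# S4 classes for the V1 cluster network model.
#
# Voltages are dimensionless: the leak reversal is 0 and the firing threshold
# is 1, so a fast-E jump of 0.02 is "2 % of the way from rest to threshold".
# All times are in milliseconds, all rates in Hz.

#' Membrane and reversal-potential constants
#'
#' Holds the single-neuron constants of the conductance-based
#' integrate-and-fire equation
#' \deqn{\tau_V \dot V = -(V - V_L) - g_E (V - V_E) - g_I (V - V_I),}
#' in dimensionless voltage units (leak reversal 0, threshold 1).
#'
#' @slot VL leak reversal (0)
#' @slot VE excitatory reversal (14/3)
#' @slot VI inhibitory reversal (-2/3)
#' @slot VT firing threshold (1)
#' @slot Vreset reset potential (0)
#' @slot tauV membrane time constant, ms (20)
#' @slot tauRef absolute refractory period, ms (1); during it the voltage is
#'   clamped at \code{Vreset} and all synaptic input is ignored
#' @export
setClass("NeuronParams",
  representation(VL = "numeric", VE = "numeric", VI = "numeric",
                 VT = "numeric", Vreset = "numeric",
                 tauV = "numeric", tauRef = "numeric"),
  prototype(VL = 0, VE = 14 / 3, VI = -2 / 3, VT = 1, Vreset = 0,
            tauV = 20, tauRef = 1))

setValidity("NeuronParams", function(object) {
  msg <- character()
  if (!(object@VI < object@VL)) msg <- c(msg, "VI must be < VL")
  if (!(object@VL <= object@Vreset)) msg <- c(msg, "VL must be <= Vreset")
  if (!(object@Vreset < object@VT)) msg <- c(msg, "Vreset must be < VT")
  if (!(object@VT < object@VE)) msg <- c(msg, "VT must be < VE")
  if (object@tauV <= 0) msg <- c(msg, "tauV must be > 0")
  if (object@tauRef < 0) msg <- c(msg, "tauRef must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synaptic kernel time constants
#'
#' All kernels are unit-integral exponentials ("alpha functions with
#' instantaneous rise"), so a synaptic weight W delivers total
#' conductance-time W regardless of the decay constant.  Fast decay times of
#' 0 select the formal instantaneous limit in which cascades (MFEs) are
#' resolved exactly at a single instant; positive values (a few ms) select
#' the finite-timescale integration mode.
#'
#' @slot tauSlow slow (NMDA-like) excitatory decay, ms (128)
#' @slot tauFastE,tauFastI fast decay times, ms (0 = instantaneous limit)
#' @export
setClass("SynapticKernels",
  representation(tauSlow = "numeric", tauFastE = "numeric",
                 tauFastI = "numeric"),
  prototype(tauSlow = 128, tauFastE = 0, tauFastI = 0))

setValidity("SynapticKernels", function(object) {
  msg <- character()
  if (object@tauSlow <= 0) msg <- c(msg, "tauSlow must be > 0")
  if (object@tauFastE < 0 || object@tauFastI < 0)
    msg <- c(msg, "fast decay times must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Dynamical state of a set of neurons
#'
#' @slot V membrane voltages (dimensionless)
#' @slot gSlow summed slow excitatory conductances (single exponential state,
#'   since all slow kernels share one decay constant)
#' @slot refractoryUntil absolute times (ms) until which each neuron is
#'   refractory (\code{-Inf} when not)
#' @slot pop population tags, "E" or "I"
#' @export
setClass("NeuronState",
  representation(V = "numeric", gSlow = "numeric",
                 refractoryUntil = "numeric", pop = "character"))

setValidity("NeuronState", function(object) {
  n <- length(object@V)
  if (length(object@gSlow) != n || length(object@refractoryUntil) != n ||
      length(object@pop) != n)
    return("all slots must have equal length")
  if (any(object@gSlow < 0)) return("gSlow must be >= 0")
  if (!all(object@pop %in% c("E", "I"))) return("pop must be 'E' or 'I'")
  TRUE
})

#' Result of resolving one cascade (multiple-firing event)
#'
#' @slot firedE,firedI indices of E/I neurons that fired during the instant
#' @slot order global firing order within the instant
#' @slot Vpre,Vpost voltage snapshots immediately before/after the instant
#' @slot slowPending slow-conductance increments earned during the instant,
#'   to be applied after it (zero for fired/refractory neurons)
#' @export
setClass("CascadeResult",
  representation(firedE = "integer", firedI = "integer", order = "integer",
                 Vpre = "numeric", Vpost = "numeric",
                 slowPending = "numeric"))

setValidity("CascadeResult", function(object) {
  if (anyDuplicated(object@order)) return("a neuron fired more than once")
  if (length(object@order) < 1) return("a cascade contains at least one spike")
  if (length(object@order) != length(object@firedE) + length(object@firedI))
    return("order must enumerate exactly the fired neurons")
  TRUE
})

#' Cluster / hypercolumn layout of the network
#'
#' @slot nHypercolumns number of hypercolumns (8)
#' @slot nOrientations orientation domains per hypercolumn (3)
#' @slot nE,nI excitatory / inhibitory neurons per cluster (128 each)
#' @export
setClass("NetworkGeometry",
  representation(nHypercolumns = "integer", nOrientations = "integer",
                 nE = "integer", nI = "integer"),
  prototype(nHypercolumns = 8L, nOrientations = 3L, nE = 128L, nI = 128L))

setValidity("NetworkGeometry", function(object) {
  v <- c(object@nHypercolumns, object@nOrientations, object@nE, object@nI)
  if (any(v < 1L)) return("all geometry fields must be positive integers")
  TRUE
})

#' Connection probabilities and coupling strengths
#'
#' Connection probability depends on the presynaptic type and on whether the
#' ordered pair lies in the same cluster, the same hypercolumn, or in
#' different hypercolumns (long-range, same orientation, E senders only).
#' Weights depend only on the pair's types and on the same-orientation /
#' same-hypercolumn indicators: 6 local parameters (4 fast, 2 slow) for pairs
#' in one hypercolumn and 4 long-range parameters (2 fast, 2 slow) for
#' same-orientation pairs in different hypercolumns.
#'
#' @slot pFromE,pFromI within-cluster connection probability from an E / I
#'   presynaptic neuron (0.20 / 0.50)
#' @slot crossClusterFactor multiplier on those probabilities for pairs in
#'   different clusters of one hypercolumn (0.5)
#' @slot pLongRange connection probability across hypercolumns (same
#'   orientation, E sender); defaults to the cross-cluster value
#' @slot sFast 2x2 matrix of local fast strengths, rows = receiver type
#'   (E, I), cols = sender type (E, I)
#' @slot sSlow length-2 local slow strengths (receiver E, I; sender E)
#' @slot lFast,lSlow length-2 long-range strengths (receiver E, I; sender E)
#' @slot delay horizontal (long-range) synaptic delay, ms (0)
#' @export
setClass("ConnectivityParams",
  representation(pFromE = "numeric", pFromI = "numeric",
                 crossClusterFactor = "numeric", pLongRange = "numeric",
                 sFast = "matrix", sSlow = "numeric",
                 lFast = "numeric", lSlow = "numeric", delay = "numeric"))

setValidity("ConnectivityParams", function(object) {
  msg <- character()
  p <- c(object@pFromE, object@pFromI, object@pLongRange,
         object@pFromE * object@crossClusterFactor,
         object@pFromI * object@crossClusterFactor)
  if (any(p < 0) || any(p > 1))
    msg <- c(msg, "connection probabilities must lie in [0, 1]")
  if (!all(dim(object@sFast) == c(2L, 2L)))
    msg <- c(msg, "sFast must be a 2x2 matrix (receiver x sender)")
  if (length(object@sSlow) != 2L || length(object@lFast) != 2L ||
      length(object@lSlow) != 2L)
    msg <- c(msg, "sSlow, lFast, lSlow must have length 2 (receiver E, I)")
  if (any(c(object@sFast, object@sSlow, object@lFast, object@lSlow) < 0))
    msg <- c(msg, "all coupling strengths must be >= 0")
  if (object@delay < 0) msg <- c(msg, "delay must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A built network: neuron table plus sparse weight matrices
#'
#' \code{Wfast} and \code{Wslow} are receiver-by-sender sparse matrices.
#' Architectural zero-structure: slow columns are all-zero for I senders;
#' both matrices are all-zero for I senders across hypercolumns; entries
#' across hypercolumns exist only for same-orientation pairs with E senders.
#'
#' @slot geometry a \linkS4class{NetworkGeometry}
#' @slot connectivity the \linkS4class{ConnectivityParams} used to build it
#' @slot neurons data.frame: \code{type} ("E"/"I"), \code{j} orientation,
#'   \code{k} hypercolumn, \code{l} within-cluster index, \code{cluster}
#' @slot Wfast,Wslow dgCMatrix weight matrices (receiver n x sender n')
#' @slot seed build seed
#' @export
setClass("CortexNetwork",
  representation(geometry = "NetworkGeometry",
                 connectivity = "ConnectivityParams",
                 neurons = "data.frame",
                 Wfast = "ANY", Wslow = "ANY", seed = "numeric"))

#' Feedforward drive parameters
#'
#' Background Poisson rates and input weights.  Every input spike is
#' delivered through the fast excitatory jump rule with weight
#' \code{sDriveQ}; in a high-gain regime \code{sDriveE} is about half the
#' local E-to-E fast coupling and the background rate lies in 250--500 Hz.
#'
#' @slot etaBkgE,etaBkgI background Poisson rates, Hz
#' @slot sDriveE,sDriveI input weights for E / I neurons
#' @export
setClass("DriveParams",
  representation(etaBkgE = "numeric", etaBkgI = "numeric",
                 sDriveE = "numeric", sDriveI = "numeric"))

setValidity("DriveParams", function(object) {
  if (object@etaBkgE < 0 || object@etaBkgI < 0) return("rates must be >= 0")
  if (object@sDriveE < 0 || object@sDriveI < 0) return("weights must be >= 0")
  TRUE
})

#' Drifting-grating stimulus specification
#'
#' The stimulus multiplies the background rate of targeted clusters:
#' \eqn{\eta^{stim}(t) = C \eta^{bkg} (1 + \sin(2\pi\omega(t - \phi_l)))}
#' with per-neuron spatial phases \eqn{\phi_l} uniform over one period, or a
#' phase-free constant \eqn{C \eta^{bkg}} when \code{phaseFree}.
#'
#' @slot targets data.frame with columns \code{j}, \code{k}, \code{contrastE};
#'   the I contrast is \code{contrastE / 3} unless \code{contrastI} is given
#' @slot omega grating temporal frequency, Hz (4)
#' @slot phaseFree logical; drop the sinusoidal phase structure
#' @slot onset stimulus onset time, ms (0)
#' @export
setClass("StimulusSpec",
  representation(targets = "data.frame", omega = "numeric",
                 phaseFree = "logical", onset = "numeric"),
  prototype(omega = 4, phaseFree = FALSE, onset = 0))

setValidity("StimulusSpec", function(object) {
  tg <- object@targets
  need <- c("j", "k", "contrastE")
  if (!all(need %in% names(tg)))
    return("targets needs columns j, k, contrastE")
  if (nrow(tg) && any(tg$contrastE < 0)) return("contrasts must be >= 0")
  if ("contrastI" %in% names(tg) && nrow(tg) && any(tg$contrastI < 0))
    return("contrasts must be >= 0")
  if (object@omega <= 0) return("omega must be > 0")
  if (object@onset < 0) return("onset must be >= 0")
  TRUE
})

#' Simulation run configuration
#'
#' @slot duration run length, ms
#' @slot sampleInterval voltage sampling interval, ms (0 = no sampling)
#' @slot sampleMode "none", "cluster" (population-mean voltages) or "full"
#'   (additionally every neuron's voltage; memory-heavy)
#' @slot seed master seed; all RNG streams derive from it
#' @slot substep relaxation substep, ms (0.1)
#' @slot delay horizontal delay override, ms (NA = use the network's)
#' @export
setClass("SimConfig",
  representation(duration = "numeric", sampleInterval = "numeric",
                 sampleMode = "character", seed = "numeric",
                 substep = "numeric", delay = "numeric"),
  prototype(sampleInterval = 0, sampleMode = "none", substep = 0.1,
            delay = NA_real_))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@sampleInterval < 0) msg <- c(msg, "sampleInterval must be >= 0")
  if (!object@sampleMode %in% c("none", "cluster", "full"))
    msg <- c(msg, "sampleMode must be none/cluster/full")
  if (object@substep <= 0) msg <- c(msg, "substep must be > 0")
  if (object@sampleInterval > 0) {
    r <- object@sampleInterval / object@substep
    if (abs(r - round(r)) > 1e-9)
      msg <- c(msg, "sampleInterval must be a multiple of substep")
  }
  if (length(msg)) msg else TRUE
})

#' Spike raster
#'
#' @slot spikes data.frame with columns \code{t} (ms), \code{Q} ("E"/"I"),
#'   \code{j} (orientation), \code{k} (hypercolumn), \code{l} (within-cluster
#'   index), \code{id} (global neuron index), \code{instant} (cascade id, NA
#'   for synthetic rasters); sorted by \code{t}
#' @slot duration run length, ms
#' @slot geometry a \linkS4class{NetworkGeometry}
#' @slot seed seed of the run that produced it (NA for synthetic rasters)
#' @export
setClass("SpikeRaster",
  representation(spikes = "data.frame", duration = "numeric",
                 geometry = "NetworkGeometry", seed = "numeric"))

setValidity("SpikeRaster", function(object) {
  sp <- object@spikes
  need <- c("t", "Q", "j", "k", "l", "id")
  if (!all(need %in% names(sp)))
    return("spikes needs columns t, Q, j, k, l, id")
  if (nrow(sp)) {
    if (is.unsorted(sp$t)) return("spikes must be sorted by t")
    if (min(sp$t) < 0 || max(sp$t) > object@duration)
      return("spike times must lie in [0, duration]")
    g <- object@geometry
    if (any(sp$j < 1 | sp$j > g@nOrientations) ||
        any(sp$k < 1 | sp$k > g@nHypercolumns))
      return("cluster indices outside geometry")
  }
  TRUE
})

#' Sampled voltage traces
#'
#' @slot time sample times, ms
#' @slot clusterV matrix (time x population), columns named "Q.j.k", holding
#'   the population-mean voltage of each cluster (the LFP proxy)
#' @slot fullV optional matrix (time x neuron) of every neuron's voltage
#' @slot geometry a \linkS4class{NetworkGeometry}
#' @export
setClass("VoltageTrace",
  representation(time = "numeric", clusterV = "matrix", fullV = "ANY",
                 geometry = "NetworkGeometry"))

#' Result of one simulation run
#'
#' @slot raster a \linkS4class{SpikeRaster}
#' @slot voltage a \linkS4class{VoltageTrace} (may hold no samples)
#' @slot manifest list echoing the full configuration and seeds, sufficient
#'   to re-run the simulation bit-identically
#' @export
setClass("SimResult",
  representation(raster = "SpikeRaster", voltage = "ANY", manifest = "list"))

#' A complete named parameter regime
#'
#' @slot name regime name
#' @slot geometry,connectivity,drive the full parameter set
#' @slot kernels synaptic kernel constants
#' @slot neuron membrane constants
#' @slot notes provenance notes (this package's regimes are tuned to the
#'   qualitative benchmark checklist, not taken from external reference values)
#' @slot checklist named logical vector of qualitative benchmark statuses
#' @export
setClass("Regime",
  representation(name = "character", geometry = "NetworkGeometry",
                 connectivity = "ConnectivityParams", drive = "DriveParams",
                 kernels = "SynapticKernels", neuron = "NeuronParams",
                 notes = "character", checklist = "logical"))

#' Specification for a synthetic raster with planted synchronous events
#'
#' @slot nE,nI population sizes
#' @slot nullRate homogeneous Poisson rate per neuron, Hz
#' @slot duration ms
#' @slot events data.frame with columns \code{t}, \code{sizeE}, \code{sizeI}
#' @slot seed RNG seed
#' @export
setClass("PlantedRasterSpec",
  representation(nE = "integer", nI = "integer", nullRate = "numeric",
                 duration = "numeric", events = "data.frame",
                 seed = "numeric"))

setValidity("PlantedRasterSpec", function(object) {
  ev <- object@events
  if (nrow(ev)) {
    if (any(ev$sizeE > object@nE) || any(ev$sizeI > object@nI))
      return("planted event sizes must not exceed the population size")
    if (any(ev$t < 0) || any(ev$t >= object@duration))
      return("planted event times must lie within the duration")
  }
  if (object@nullRate < 0) return("nullRate must be >= 0")
  TRUE
})
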