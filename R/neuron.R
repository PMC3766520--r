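# Single-neuron membrane dynamics in the instantaneous fast-synapse limit.

#' Instantaneous synaptic voltage jump
#'
#' Exact integral of the membrane equation across a delta conductance of
#' area \code{w} pulled toward \code{reversal}:
#' \deqn{V' = V_{rev} + (V - V_{rev}) e^{-w/\tau_V}.}
#' This is the unique limit of the conductance-based dynamics as the fast
#' synaptic decay time goes to zero: during the (vanishing) kernel the leak
#' and slow currents contribute nothing, and integrating
#' \eqn{\tau_V \dot V = -g(t)(V - V_{rev})} over the kernel leaves only its
#' total area \code{w} in the exponent.  The jump moves \code{v} strictly
#' toward the reversal and never past it; inhibition is encoded by choosing
#' the inhibitory reversal, never by a negative weight.
#'
#' @param v membrane voltage(s)
#' @param w synaptic weight (conductance-time area), >= 0
#' @param reversal reversal potential of the synapse
#' @param tauV membrane time constant, ms
#' @return the post-jump voltage(s)
#' @examples
#' p <- neuronParams()
#' voltageJump(0, 20 * log(2), p@VE, p@tauV)  # exactly half-way to V_E
#' @export
voltageJump <- function(v, w, reversal, tauV = 20) {
  if (any(w < 0))
    stop("synaptic weights must be >= 0 (inhibition is encoded by the reversal)")
  reversal + (v - reversal) * exp(-w / tauV)
}

#' Relax neurons between synaptic events
#'
#' Advances membrane voltages under leak plus the exponentially decaying slow
#' excitatory conductance, with no fast events inside the interval.  The
#' interval is cut into substeps of at most \code{substep} ms; within each,
#' the slow conductance is frozen at its substep-midpoint value and the
#' voltage is updated by the exact exponential step toward the frozen
#' equilibrium \eqn{(V_L + g V_E) / (1 + g)}.  If a voltage would cross
#' threshold the crossing time is solved in closed form inside the substep
#' and the neuron is stopped there.
#'
#' @param state a \linkS4class{NeuronState}
#' @param params a \linkS4class{NeuronParams}
#' @param kernels a \linkS4class{SynapticKernels} (for the slow decay time)
#' @param dt interval length, ms (>= 0; 0 is the identity)
#' @param substep maximum integration substep, ms
#' @param stopAtThreshold if TRUE (default), stop a neuron at its threshold
#'   crossing and report the time; if FALSE integrate freely (for computing
#'   subthreshold equilibria)
#' @return list with \code{state} (advanced \linkS4class{NeuronState}) and
#'   \code{crossing} (numeric vector of crossing times, NA where none)
#' @export
relaxMembrane <- function(state, params = neuronParams(),
                          kernels = synapticKernels(), dt,
                          substep = 0.1, stopAtThreshold = TRUE) {
  stopifnot(dt >= 0)
  n <- length(state@V)
  V <- state@V
  g <- state@gSlow
  crossing <- rep(NA_real_, n)
  if (dt == 0) return(list(state = state, crossing = crossing))

  nStep <- max(1L, ceiling(dt / substep))
  h <- dt / nStep
  decHalf <- exp(-0.5 * h / kernels@tauSlow)
  dec <- exp(-h / kernels@tauSlow)
  active <- rep(TRUE, n)
  t <- 0
  for (s in seq_len(nStep)) {
    gm <- g * decHalf
    denom <- 1 + gm
    Vs <- (params@VL + gm * params@VE) / denom
    f <- exp(-denom * h / params@tauV)
    Vnew <- Vs + (V - Vs) * f
    if (stopAtThreshold) {
      hit <- active & Vnew >= params@VT & V < params@VT
      if (any(hit)) {
        tc <- -params@tauV / denom[hit] *
          log((params@VT - Vs[hit]) / (V[hit] - Vs[hit]))
        crossing[hit] <- t + tc
        V[hit] <- params@VT
        active[hit] <- FALSE
      }
    }
    V[active] <- Vnew[active]
    g[active] <- g[active] * dec
    t <- t + h
  }
  new("NeuronState", V = V, gSlow = g,
      refractoryUntil = state@refractoryUntil, pop = state@pop) -> st
  list(state = st, crossing = crossing)
}

#' Reset a neuron after a spike
#'
#' Sets the voltage to the reset potential and starts the absolute
#' refractory clock: until \code{t + tauRef} the neuron integrates nothing
#' and ignores all synaptic input.  With \code{tauRef = 0} the neuron
#' re-integrates immediately, but the single-firing-per-instant rule of
#' cascade resolution still guarantees at most one spike per instant.
#'
#' @param state a \linkS4class{NeuronState}
#' @param which indices of the neurons that spiked
#' @param t spike time, ms
#' @param params a \linkS4class{NeuronParams}
#' @return the updated \linkS4class{NeuronState}
#' @export
applyReset <- function(state, which, t, params = neuronParams()) {
  state@V[which] <- params@Vreset
  state@refractoryUntil[which] <- t + params@tauRef
  state
}
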