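# Feedforward Poisson drive: background plus drifting-grating stimulus.

#' Build a drifting-grating stimulus specification
#'
#' Targets are clusters (orientation j, hypercolumn k) with an excitatory
#' contrast; the inhibitory contrast defaults to a third of the excitatory
#' one, modelling the excess of orientation-tuned input to the excitatory
#' population.
#'
#' @param j,k orientation and hypercolumn indices of the targeted clusters
#'   (recycled to a common length)
#' @param contrastE excitatory contrast(s), >= 0
#' @param contrastI inhibitory contrast(s); default \code{contrastE / 3}
#' @param omega grating temporal frequency, Hz
#' @param phaseFree drop the per-neuron spatial phase (constant-rate variant)
#' @param onset stimulus onset, ms
#' @return a validated \linkS4class{StimulusSpec}
#' @examples
#' stimulusSpec(j = 1, k = 1:3, contrastE = 0.75)   # 3-cluster grating
#' @export
stimulusSpec <- function(j = integer(0), k = integer(0),
                         contrastE = numeric(0), contrastI = contrastE / 3,
                         omega = 4, phaseFree = FALSE, onset = 0) {
  nT <- max(length(j), length(k), length(contrastE), 0L)
  tg <- data.frame(j = rep_len(as.integer(j), nT),
                   k = rep_len(as.integer(k), nT),
                   contrastE = rep_len(contrastE, nT),
                   contrastI = rep_len(contrastI, nT))
  new("StimulusSpec", targets = tg, omega = omega, phaseFree = phaseFree,
      onset = onset)
}

#' Instantaneous feedforward Poisson rate of one neuron
#'
#' \deqn{\eta(t) = \eta^{bkg} + C \, \eta^{bkg} (1 + \sin(2\pi\omega(t - \phi)))}
#' for neurons in targeted clusters (after stimulus onset), and the bare
#' background rate otherwise.  In the phase-free variant the stimulus term
#' is the constant \eqn{C\,\eta^{bkg}} (its time average).
#'
#' @param Q population type, "E" or "I"
#' @param j,k cluster indices
#' @param t time, ms (vectorized)
#' @param drive a \linkS4class{DriveParams}
#' @param stimulus a \linkS4class{StimulusSpec} or NULL (background only)
#' @param phi spatial phase of the neuron, ms in [0, 1000/omega)
#' @return rate(s) in Hz, always >= 0
#' @export
driveRate <- function(Q, j, k, t, drive, stimulus = NULL, phi = 0) {
  stopifnot(all(t >= 0))
  bkg <- if (Q == "E") drive@etaBkgE else drive@etaBkgI
  if (is.null(stimulus) || nrow(stimulus@targets) == 0L)
    return(rep_len(bkg, length(t)))
  tg <- stimulus@targets
  hit <- which(tg$j == j & tg$k == k)
  if (!length(hit)) return(rep_len(bkg, length(t)))
  C <- if (Q == "E") tg$contrastE[hit[1]] else tg$contrastI[hit[1]]
  out <- rep_len(bkg, length(t))
  on <- t >= stimulus@onset
  if (stimulus@phaseFree) {
    out[on] <- bkg * (1 + C)
  } else {
    period <- 1000 / stimulus@omega
    out[on] <- bkg + C * bkg * (1 + sin(2 * pi * (t[on] - phi) / period))
  }
  out
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Candidate arrivals are drawn at the supplied supremum rate and accepted
#' with probability rate/supremum; the result is an exact sample of the
#' inhomogeneous Poisson process.  Reproducible given the seed.
#'
#' @param rateFn function(t_ms) -> rate in Hz, bounded by \code{supRate} on
#'   the horizon
#' @param horizon sampling horizon, ms
#' @param supRate supremum of the rate on the horizon, Hz; defaults to a
#'   grid-estimated bound (fails loudly if the rate exceeds it)
#' @param seed RNG seed
#' @return numeric vector of spike times in (0, horizon]
#' @export
sampleInputSpikes <- function(rateFn, horizon, supRate = NULL, seed = 1) {
  if (is.null(supRate)) {
    grid <- seq(0, horizon, length.out = 2048)
    supRate <- max(rateFn(grid)) * 1.0001
  }
  if (!is.finite(supRate) || supRate < 0)
    stop("rate supremum must be finite and >= 0")
  if (supRate == 0) return(numeric(0))
  lam <- supRate / 1000  # per ms
  withSeed(seed, {
    # draw candidates in blocks
    out <- numeric(0)
    t <- 0
    repeat {
      nBlock <- max(64L, ceiling(lam * (horizon - t) * 1.5))
      gaps <- rexp(nBlock, lam)
      cand <- t + cumsum(gaps)
      crossed <- any(cand > horizon)
      cand <- cand[cand <= horizon]
      if (length(cand)) {
        r <- rateFn(cand)
        if (any(r > supRate * (1 + 1e-9)))
          stop("rate exceeds the supplied supremum; thinning invalid")
        if (any(r < 0)) stop("negative rate")
        acc <- runif(length(cand)) < r / supRate
        out <- c(out, cand[acc])
        t <- cand[length(cand)]
      }
      # once a candidate fell beyond the horizon the sequence is complete;
      # regenerating from the last kept candidate would double-sample the
      # tail of the interval
      if (crossed) break
    }
    out
  })
}
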