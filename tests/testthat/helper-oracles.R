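# Independent oracles used across the suite.

# Brute-force finite-tau_fast simulation of a small population: the fast
# kernels are explicit decaying conductances and the membrane ODE is
# integrated on a fine grid.  Used as the reference for cascade resolution.
finiteTauCascade <- function(V0, pop, W, tauf, params = neuronParams(),
                             stepsPerTau = 200) {
  n <- length(V0)
  V <- V0; gE <- numeric(n); gI <- numeric(n)
  fired <- rep(FALSE, n); ord <- integer(0)
  for (i in which(V0 >= params@VT)) {
    fired[i] <- TRUE; ord <- c(ord, i)
    w <- W[, i] / tauf
    if (pop[i] == "E") gE <- gE + w else gI <- gI + w
  }
  V[fired] <- params@Vreset
  dt <- tauf / stepsPerTau
  t <- 0; tLast <- 0
  decay <- exp(-dt / tauf)
  while (t < tLast + 40 * tauf) {
    denom <- 1 + gE + gI
    Vs <- (params@VL + gE * params@VE + gI * params@VI) / denom
    f <- exp(-denom * dt / params@tauV)
    Vn <- Vs + (V - Vs) * f
    Vn[fired] <- params@Vreset
    gE <- gE * decay; gI <- gI * decay
    t <- t + dt
    hit <- which(!fired & Vn >= params@VT)
    while (length(hit)) {
      i <- hit[which.max(Vn[hit])]
      fired[i] <- TRUE; ord <- c(ord, i); tLast <- t
      Vn[i] <- params@Vreset
      w <- W[, i] / tauf
      add <- !fired
      if (pop[i] == "E") gE[add] <- gE[add] + w[add]
      else gI[add] <- gI[add] + w[add]
      hit <- which(!fired & Vn >= params@VT)
    }
    V <- Vn
  }
  list(order = ord, V = V)
}

# High-resolution numeric integration of the membrane ODE under a
# prescribed conductance trajectory gFn(t) (toward V_E), no threshold.
odeMembrane <- function(V0, gFn, tEnd, params = neuronParams(), dt = 1e-4) {
  nStep <- ceiling(tEnd / dt)
  V <- V0; t <- 0
  for (s in seq_len(nStep)) {
    g1 <- gFn(t); g2 <- gFn(t + dt / 2); g3 <- gFn(t + dt)
    f <- function(v, g) (-(v - params@VL) - g * (v - params@VE)) / params@tauV
    k1 <- f(V, g1); k2 <- f(V + dt / 2 * k1, g2)
    k3 <- f(V + dt / 2 * k2, g2); k4 <- f(V + dt * k3, g3)
    V <- V + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  V
}

# Direct double-loop cross-covariance oracle over all ordered neuron pairs.
xcovDoubleLoop <- function(raster, Q, Qp, A, B, tauMax, dt) {
  g <- raster@geometry
  L <- as.integer(round(tauMax / dt))
  nBin <- max(1L, ceiling(raster@duration / dt - 1e-12))
  sp <- raster@spikes
  nt <- MFEsim:::makeNeuronTable(g)
  binned <- function(id) {
    s <- sp[sp$id == id, ]
    tabulate(pmin(floor(s$t / dt), nBin - 1L) + 1L, nbins = nBin)
  }
  trig <- nt$id[nt$type == Q]
  raw <- numeric(2 * L + 1)
  msub <- numeric(2 * L + 1)
  cache <- list()
  getb <- function(id) {
    key <- as.character(id)
    if (is.null(cache[[key]])) cache[[key]] <<- binned(id)
    cache[[key]]
  }
  for (a in trig) {
    for (b in nt$id[nt$type == Qp]) {
      if (a == b) next
      if ((nt$j[a] == nt$j[b]) != (A == 1)) next
      if ((nt$k[a] == nt$k[b]) != (B == 1)) next
      xa <- getb(a); xb <- getb(b)
      xac <- xa - mean(xa); xbc <- xb - mean(xb)
      for (l in -L:L) {
        if (l >= 0) {
          s1 <- sum(xa[(1 + l):nBin] * xb[1:(nBin - l)])
          s2 <- sum(xac[(1 + l):nBin] * xbc[1:(nBin - l)])
        } else {
          s1 <- sum(xa[1:(nBin + l)] * xb[(1 - l):nBin])
          s2 <- sum(xac[1:(nBin + l)] * xbc[(1 - l):nBin])
        }
        raw[L + 1 + l] <- raw[L + 1 + l] + s1
        msub[L + 1 + l] <- msub[L + 1 + l] + s2
      }
    }
  }
  list(tau = (-L:L) * dt, raw = raw * dt, meanSub = msub * dt)
}

# quick small-network fixture shared by engine tests
smallTestNetwork <- function(seed = 1, nE = 32, nI = 32) {
  buildNetwork(networkGeometry(1, 1, nE, nI), connectivityParams(), seed)
}
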