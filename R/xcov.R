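# Pairwise spike statistics across orientation/hypercolumn classes.
#
# C(Q, Q', A, B, tau) sums, over all ordered neuron pairs whose orientation
# match equals A and hypercolumn match equals B, the lagged products of their
# binned spike trains.  The raw product sum is nonnegative by construction;
# background anticorrelation between unlike orientations is only visible
# after mean subtraction, so both variants are computed and the
# mean-subtracted one is the default for inspection.

#' Cross-covariance of population spiking across pair classes
#'
#' @slot tau lag grid, ms
#' @slot raw raw lagged product sums (times dt)
#' @slot meanSub mean-subtracted variant
#' @slot meta list: Q, Qp, A, B, dt, number of contributing ordered pairs
#' @export
setClass("CrossCovResult",
  representation(tau = "numeric", raw = "numeric", meanSub = "numeric",
                 meta = "list"))

setMethod("show", "CrossCovResult", function(object) {
  m <- object@meta
  cat(sprintf("CrossCovResult C(%s,%s,A=%d,B=%d): %d lags, dt=%g ms, %d ordered pairs\n",
              m$Q, m$Qp, m$A, m$B, length(object@tau), m$dt, m$nPairs))
})

# lagged product sums of two equal-length series for lags -L..L,
# zero-padded outside the series; integer-valued inputs stay exact
lagProducts <- function(x, y, L) {
  T <- length(x)
  out <- numeric(2 * L + 1)
  for (l in 0:L) {
    # tau = +l : sum_t x[t] y[t - l]
    if (l < T) {
      out[L + 1 + l] <- sum(x[(1 + l):T] * y[1:(T - l)])
      if (l > 0) out[L + 1 - l] <- sum(x[1:(T - l)] * y[(1 + l):T])
    }
  }
  out
}

#' Cross-covariance between spike trains selected by orientation and
#' hypercolumn match
#'
#' Sums lagged products of 1-ms-binned (by default) spike trains over all
#' ordered pairs of neurons of types (Q, Q') whose orientation-match
#' indicator equals A and hypercolumn-match indicator equals B, excluding
#' the pairing of a neuron with itself.  Both the raw product sum (scaled
#' by dt) and the mean-subtracted variant are returned.
#'
#' @param x a \linkS4class{SpikeRaster} or \linkS4class{SimResult}
#' @param Q,Qp trigger and partner population types ("E"/"I")
#' @param A 1 = same orientation, 0 = different
#' @param B 1 = same hypercolumn, 0 = different
#' @param tauMax maximum lag, ms (multiple of dt)
#' @param dt bin width, ms
#' @param burnIn initial ms excluded
#' @return a \linkS4class{CrossCovResult}
#' @export
crossCovariance <- function(x, Q = "E", Qp = "E", A = 1, B = 0,
                            tauMax = 500, dt = 1, burnIn = 0) {
  if (is(x, "SimResult")) x <- x@raster
  stopifnot(Q %in% c("E", "I"), Qp %in% c("E", "I"), A %in% 0:1, B %in% 0:1)
  L <- tauMax / dt
  if (abs(L - round(L)) > 1e-9) stop("tauMax must be a multiple of dt")
  L <- as.integer(round(L))
  g <- x@geometry
  J <- g@nOrientations; K <- g@nHypercolumns
  nQ <- if (Q == "E") g@nE else g@nI
  nQp <- if (Qp == "E") g@nE else g@nI

  # number of ordered cluster pairs in the class
  nClPair <- switch(paste0(A, B),
                    "11" = J * K,
                    "10" = J * K * (K - 1),
                    "01" = J * K * (J - 1),
                    "00" = J * K * (J - 1) * (K - 1))
  if (nClPair == 0)
    stop(sprintf("no neuron pairs in class (A=%d, B=%d) for this geometry",
                 A, B))
  nPairs <- nClPair * nQ * nQp - (if (Q == Qp && A == 1 && B == 1)
    J * K * nQ else 0)

  # raster restricted to the epoch
  sp <- x@spikes
  keep <- sp$t >= burnIn
  sub <- new("SpikeRaster", spikes = transform(sp[keep, ], t = t - burnIn),
             duration = x@duration - burnIn, geometry = g, seed = x@seed)
  cnt <- binSpikes(sub, dt)                 # T x (2 per cluster)
  T <- nrow(cnt)

  colFor <- function(QQ) {
    cj <- (seq_len(J * K) - 1L) %% J + 1L
    ck <- (seq_len(J * K) - 1L) %/% J + 1L
    sprintf("%s.%d.%d", QQ, cj, ck)
  }
  Sx <- cnt[, colFor(Q), drop = FALSE]      # trigger cluster series
  Sy <- cnt[, colFor(Qp), drop = FALSE]
  cj <- (seq_len(J * K) - 1L) %% J + 1L
  ck <- (seq_len(J * K) - 1L) %/% J + 1L

  classSum <- function(X, Y) {
    # sum over ordered cluster pairs (c, c') with delta_jj' = A, delta_kk' = B
    acc <- numeric(2 * L + 1)
    if (A == 1 && B == 1) {
      for (cc in seq_len(J * K)) acc <- acc + lagProducts(X[, cc], Y[, cc], L)
    } else if (A == 1 && B == 0) {
      for (jj in seq_len(J)) {
        cls <- which(cj == jj)
        Tx <- rowSums(X[, cls, drop = FALSE])
        Ty <- rowSums(Y[, cls, drop = FALSE])
        acc <- acc + lagProducts(Tx, Ty, L)
        for (cc in cls) acc <- acc - lagProducts(X[, cc], Y[, cc], L)
      }
    } else if (A == 0 && B == 1) {
      for (kk in seq_len(K)) {
        cls <- which(ck == kk)
        Ux <- rowSums(X[, cls, drop = FALSE])
        Uy <- rowSums(Y[, cls, drop = FALSE])
        acc <- acc + lagProducts(Ux, Uy, L)
        for (cc in cls) acc <- acc - lagProducts(X[, cc], Y[, cc], L)
      }
    } else {
      Gx <- rowSums(X); Gy <- rowSums(Y)
      acc <- lagProducts(Gx, Gy, L)
      for (jj in seq_len(J)) {
        cls <- which(cj == jj)
        acc <- acc - lagProducts(rowSums(X[, cls, drop = FALSE]),
                                 rowSums(Y[, cls, drop = FALSE]), L)
      }
      for (kk in seq_len(K)) {
        cls <- which(ck == kk)
        acc <- acc - lagProducts(rowSums(X[, cls, drop = FALSE]),
                                 rowSums(Y[, cls, drop = FALSE]), L)
      }
      for (cc in seq_len(J * K)) acc <- acc + lagProducts(X[, cc], Y[, cc], L)
    }
    acc
  }

  raw <- classSum(Sx, Sy)
  Sxc <- sweep(Sx, 2, colMeans(Sx)); Syc <- sweep(Sy, 2, colMeans(Sy))
  msub <- classSum(Sxc, Syc)

  if (Q == Qp && A == 1 && B == 1) {
    # exclude each neuron paired with itself
    spQ <- sub@spikes[sub@spikes$Q == Q, ]
    bins <- pmin(floor(spQ$t / dt), T - 1L) + 1L
    for (nid in unique(spQ$id)) {
      bn <- bins[spQ$id == nid]
      tb <- table(bn)
      b <- as.integer(names(tb)); cvals <- as.numeric(tb)
      dmat <- outer(b, b, "-")
      pmat <- outer(cvals, cvals)
      selD <- abs(dmat) <= L
      ac <- numeric(2 * L + 1)
      dd <- dmat[selD] + L + 1L
      pp <- pmat[selD]
      for (z in seq_along(dd)) ac[dd[z]] <- ac[dd[z]] + pp[z]
      raw <- raw - ac
      # centered autocorrelation of this neuron's train:
      # ac_c(l) = ac(l) - m*(S - head(l) + cum(T-l)) + (T-l) m^2
      S <- sum(cvals)
      m <- S / T
      cumv <- c(0, cumsum(tabulate(bn, nbins = T)))  # cumv[l+1] = spikes in 1..l
      acC <- numeric(2 * L + 1)
      for (l in 0:min(L, T - 1L)) {
        corr <- m * (S - cumv[l + 1L] + cumv[T - l + 1L]) - (T - l) * m * m
        acC[L + 1L + l] <- ac[L + 1L + l] - corr
        acC[L + 1L - l] <- ac[L + 1L - l] - corr
      }
      msub <- msub - acC
    }
  }

  new("CrossCovResult", tau = (-L:L) * dt, raw = raw * dt,
      meanSub = msub * dt,
      meta = list(Q = Q, Qp = Qp, A = A, B = B, dt = dt, nPairs = nPairs,
                  T = T, burnIn = burnIn))
}

#' Spike-triggered voltage distribution
#'
#' @slot tau lag grid, ms
#' @slot vMid voltage-bin midpoints
#' @slot density matrix (voltage bin x lag); each lag column sums to the
#'   trigger count (or 1 when normalized)
#' @slot mean,sd per-lag mean and SD of the partner voltages
#' @slot nTriggers number of trigger spikes used
#' @slot meta list of the selection parameters
#' @export
setClass("STVResult",
  representation(tau = "numeric", vMid = "numeric", density = "matrix",
                 mean = "numeric", sd = "numeric", nTriggers = "integer",
                 meta = "list"))

setMethod("show", "STVResult", function(object) {
  cat(sprintf("STVResult: %d lags x %d voltage bins, %d triggers\n",
              length(object@tau), length(object@vMid), object@nTriggers))
})

#' Distribution of partner-population voltages around trigger spikes
#'
#' For every spike of the trigger population and every lag tau, collects
#' the voltages of all partner-class neurons (orientation match A,
#' hypercolumn match B, trigger neuron itself excluded) at time t - tau,
#' histogrammed over a voltage grid, with per-lag mean and SD.
#'
#' @param x a \linkS4class{SimResult} with full voltage sampling, or a
#'   \linkS4class{SpikeRaster} plus \code{vtrace}
#' @param vtrace a \linkS4class{VoltageTrace} with \code{fullV} (required
#'   when \code{x} is a raster)
#' @param Q,Qp trigger and partner types
#' @param A,B orientation / hypercolumn match indicators
#' @param tauGrid lags, ms (positive lags look back in time)
#' @param vBreaks voltage histogram breaks
#' @param burnIn initial ms excluded from triggers
#' @param maxTriggers subsample at most this many triggers (deterministic
#'   thinning)
#' @param trim drop triggers whose lag window is not covered by the
#'   sampling; if FALSE such triggers raise an error
#' @param normalize divide each lag column by the trigger count
#' @return an \linkS4class{STVResult}
#' @export
spikeTriggeredVoltage <- function(x, vtrace = NULL, Q = "E", Qp = "E",
                                  A = 1, B = 0,
                                  tauGrid = seq(-50, 50, by = 2),
                                  vBreaks = seq(-2 / 3, 1, length.out = 51),
                                  burnIn = 500, maxTriggers = 5000,
                                  trim = FALSE, normalize = TRUE) {
  if (is(x, "SimResult")) { vtrace <- x@voltage; x <- x@raster }
  if (is.null(vtrace) || is.null(vtrace@fullV))
    stop("spikeTriggeredVoltage needs full per-neuron voltage sampling")
  g <- x@geometry
  J <- g@nOrientations; K <- g@nHypercolumns
  tt <- vtrace@time
  dtS <- if (length(tt) > 1) tt[2] - tt[1] else stop("too few samples")

  nt <- makeNeuronTable(g)
  partnersOf <- function(jj, kk) {
    selJ <- if (A == 1) nt$j == jj else nt$j != jj
    selK <- if (B == 1) nt$k == kk else nt$k != kk
    which(nt$type == Qp & selJ & selK)
  }
  partnerCache <- list()

  sp <- x@spikes
  trig <- sp[sp$Q == Q & sp$t >= burnIn, ]
  if (nrow(trig) > maxTriggers) {
    idx <- unique(round(seq(1, nrow(trig), length.out = maxTriggers)))
    trig <- trig[idx, ]
  }
  if (nrow(trig) == 0) {
    return(new("STVResult", tau = tauGrid,
               vMid = (head(vBreaks, -1) + tail(vBreaks, -1)) / 2,
               density = matrix(0, length(vBreaks) - 1, length(tauGrid)),
               mean = rep(NA_real_, length(tauGrid)),
               sd = rep(NA_real_, length(tauGrid)), nTriggers = 0L,
               meta = list(Q = Q, Qp = Qp, A = A, B = B)))
  }

  nV <- length(vBreaks) - 1
  dens <- matrix(0, nV, length(tauGrid))
  sumV <- sumV2 <- cntV <- numeric(length(tauGrid))
  okTrig <- rep(TRUE, nrow(trig))
  for (z in seq_len(nrow(trig))) {
    key <- paste(trig$j[z], trig$k[z])
    if (is.null(partnerCache[[key]]))
      partnerCache[[key]] <- partnersOf(trig$j[z], trig$k[z])
    part <- setdiff(partnerCache[[key]], trig$id[z])
    if (!length(part)) next
    idxs <- round((trig$t[z] - tauGrid - tt[1]) / dtS) + 1
    if (any(idxs < 1 | idxs > length(tt))) {
      if (!trim) stop("missing voltage samples for a trigger's lag window")
      okTrig[z] <- FALSE
      next
    }
    for (q in seq_along(tauGrid)) {
      vv <- vtrace@fullV[idxs[q], part]
      h <- findInterval(vv, vBreaks, rightmost.closed = TRUE)
      h <- h[h >= 1 & h <= nV]
      dens[, q] <- dens[, q] + tabulate(h, nbins = nV)
      sumV[q] <- sumV[q] + sum(vv)
      sumV2[q] <- sumV2[q] + sum(vv^2)
      cntV[q] <- cntV[q] + length(vv)
    }
  }
  nT <- sum(okTrig)
  mu <- ifelse(cntV > 0, sumV / cntV, NA_real_)
  sdv <- ifelse(cntV > 1, sqrt(pmax(sumV2 / cntV - mu^2, 0)), NA_real_)
  if (normalize && nT > 0) dens <- dens / nT
  new("STVResult", tau = tauGrid,
      vMid = (head(vBreaks, -1) + tail(vBreaks, -1)) / 2,
      density = dens, mean = mu, sd = sdv, nTriggers = as.integer(nT),
      meta = list(Q = Q, Qp = Qp, A = A, B = B, dtSample = dtS))
}
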