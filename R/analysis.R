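# Raster statistics: binning, the binomial "95 % rule" for MFE detection,
# MFE/non-MFE decomposition, LFP-proxy spectra, trial variability, rates.

#' Bin a spike raster
#'
#' Left-closed, right-open time bins.  Counts are returned as a matrix
#' (bins x groups); grouping is per (population, cluster) by default.
#'
#' @param x a \linkS4class{SpikeRaster} (or \linkS4class{SimResult})
#' @param binMs bin width, ms
#' @param scope "cluster" (one column per population per cluster, named
#'   "Q.j.k") or "population" (one column per population, network-wide)
#' @return matrix of counts with attributes \code{binMs} and \code{starts}
#'   (bin start times); \code{sum(counts) == nSpikes(x)}
#' @examples
#' r <- makePlantedRaster(plantedRasterSpec(nE = 8, nI = 0, nullRate = 20,
#'                                          duration = 1000, seed = 1))
#' colSums(binSpikes(r$raster, 1))
#' @export
binSpikes <- function(x, binMs = 1, scope = c("cluster", "population")) {
  if (is(x, "SimResult")) x <- x@raster
  scope <- match.arg(scope)
  stopifnot(binMs > 0)
  g <- x@geometry
  nBin <- max(1L, ceiling(x@duration / binMs - 1e-12))
  sp <- x@spikes
  bin <- pmin(floor(sp$t / binMs), nBin - 1L) + 1L
  if (scope == "cluster") {
    J <- g@nOrientations
    cl <- (sp$k - 1L) * J + sp$j
    grp <- (cl - 1L) * 2L + ifelse(sp$Q == "E", 1L, 2L)
    nG <- nClusters(g) * 2L
    cj <- (seq_len(nClusters(g)) - 1L) %% J + 1L
    ck <- (seq_len(nClusters(g)) - 1L) %/% J + 1L
    nm <- character(nG)
    nm[2 * seq_len(nClusters(g)) - 1L] <- sprintf("E.%d.%d", cj, ck)
    nm[2 * seq_len(nClusters(g))] <- sprintf("I.%d.%d", cj, ck)
  } else {
    grp <- ifelse(sp$Q == "E", 1L, 2L)
    nG <- 2L
    nm <- c("E", "I")
  }
  counts <- matrix(0L, nBin, nG, dimnames = list(NULL, nm))
  if (nrow(sp)) {
    tb <- table(factor(bin, levels = seq_len(nBin)),
                factor(grp, levels = seq_len(nG)))
    counts[] <- as.integer(tb)
  }
  attr(counts, "binMs") <- binMs
  attr(counts, "starts") <- (seq_len(nBin) - 1) * binMs
  counts
}

#' MFE spike-count cutoff from the binomial null
#'
#' Under the null that all neurons fire independently and all spikes are
#' equally likely at all times, the count in a bin is Binomial(n, rate*bin).
#' The cutoff is the smallest integer c whose binomial CDF reaches the
#' percentile; a bin is an MFE-bin iff its count is strictly greater than c
#' (more spikes than the 95th percentile).
#'
#' @param nNeurons population size
#' @param meanRateHz mean per-neuron firing rate, Hz
#' @param binMs bin width, ms
#' @param percentile null percentile (0.95 for the "95 % rule")
#' @return integer cutoff
#' @examples
#' mfeCutoff(128, 5, 1)   # low-rate population: cutoff 2
#' @export
mfeCutoff <- function(nNeurons, meanRateHz, binMs = 1, percentile = 0.95) {
  stopifnot(nNeurons >= 1, meanRateHz >= 0, binMs > 0)
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must lie strictly between 0 and 1")
  p <- min(1, meanRateHz * binMs / 1000)
  as.integer(qbinom(percentile, size = as.integer(nNeurons), prob = p))
}

#' Detect multiple-firing events by the 95 % rule
#'
#' Flags every bin whose count strictly exceeds the cutoff; one event per
#' flagged bin, or per maximal run of adjacent flagged bins when merging.
#' Magnitude is the contained spike count.  E and I populations are
#' detected separately (their magnitude histograms are reported separately).
#'
#' @param counts a one-column slice or multi-column matrix from
#'   \code{\link{binSpikes}}
#' @param cutoff integer cutoff(s), one per column (recycled); see
#'   \code{\link{mfeCutoff}}
#' @param mergeAdjacent merge runs of adjacent flagged bins into one event
#' @return data.frame with columns \code{column}, \code{bin} (first bin,
#'   1-based), \code{t} (bin start, ms), \code{nBins}, \code{magnitude}
#' @export
detectMFEs <- function(counts, cutoff, mergeAdjacent = FALSE) {
  counts <- as.matrix(counts)
  cutoff <- rep_len(as.integer(cutoff), ncol(counts))
  binMs <- attr(counts, "binMs"); if (is.null(binMs)) binMs <- 1
  starts <- attr(counts, "starts")
  if (is.null(starts)) starts <- (seq_len(nrow(counts)) - 1) * binMs
  out <- list()
  cn <- colnames(counts); if (is.null(cn)) cn <- as.character(seq_len(ncol(counts)))
  for (cc in seq_len(ncol(counts))) {
    flag <- counts[, cc] > cutoff[cc]
    if (!any(flag)) next
    if (mergeAdjacent) {
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      beg <- ends - r$lengths + 1L
      keep <- which(r$values)
      ev <- data.frame(bin = beg[keep], nBins = r$lengths[keep])
      ev$magnitude <- vapply(seq_len(nrow(ev)), function(z)
        sum(counts[ev$bin[z]:(ev$bin[z] + ev$nBins[z] - 1L), cc]), numeric(1))
    } else {
      w <- which(flag)
      ev <- data.frame(bin = w, nBins = 1L, magnitude = counts[w, cc])
    }
    ev$t <- starts[ev$bin]
    ev$column <- cn[cc]
    out[[length(out) + 1L]] <- ev[, c("column", "bin", "t", "nBins",
                                      "magnitude")]
  }
  if (!length(out))
    return(data.frame(column = character(0), bin = integer(0),
                      t = numeric(0), nBins = integer(0),
                      magnitude = numeric(0)))
  do.call(rbind, out)
}

#' Fraction of spikes that fall in MFE-bins
#'
#' The MFE-spike fraction measures the homogeneity of the population spike
#' pattern: near 0 when spikes are scattered as under the independent
#' binomial null, near 1 when most spikes arrive in barrages.
#'
#' @inheritParams detectMFEs
#' @return named numeric vector, one fraction per column (0 when a column
#'   has no spikes), plus an \code{"total"} element pooling all columns
#' @export
mfeSpikeFraction <- function(counts, cutoff) {
  counts <- as.matrix(counts)
  cutoff <- rep_len(as.integer(cutoff), ncol(counts))
  frac <- numeric(ncol(counts))
  inMfe <- 0; all <- 0
  for (cc in seq_len(ncol(counts))) {
    tot <- sum(counts[, cc])
    mf <- sum(counts[counts[, cc] > cutoff[cc], cc])
    frac[cc] <- if (tot > 0) mf / tot else 0
    inMfe <- inMfe + mf; all <- all + tot
  }
  names(frac) <- colnames(counts)
  c(frac, total = if (all > 0) inMfe / all else 0)
}

#' Power spectral density of the LFP proxy
#'
#' Averages periodograms over non-overlapping windows of the cluster's
#' population-mean voltage (the package's LFP stand-in).  Frequency
#' resolution is 1000/windowMs Hz.
#'
#' @param vtrace a \linkS4class{VoltageTrace} (cluster-mean sampling or
#'   better)
#' @param cluster cluster index (j, k) as a length-2 vector
#' @param population "all" (mean of E and I population means), "E" or "I"
#' @param windowMs window length, ms; the trace must cover at least one
#'   window
#' @return data.frame with columns \code{freq} (Hz) and \code{power}
#' @export
lfpPSD <- function(vtrace, cluster = c(1, 1),
                   population = c("all", "E", "I"), windowMs = 512) {
  population <- match.arg(population)
  stopifnot(is(vtrace, "VoltageTrace"))
  dtMs <- if (length(vtrace@time) > 1) diff(vtrace@time[1:2]) else
    stop("voltage trace too short")
  cnE <- sprintf("E.%d.%d", cluster[1], cluster[2])
  cnI <- sprintf("I.%d.%d", cluster[1], cluster[2])
  x <- switch(population,
              all = (vtrace@clusterV[, cnE] + vtrace@clusterV[, cnI]) / 2,
              E = vtrace@clusterV[, cnE],
              I = vtrace@clusterV[, cnI])
  W <- round(windowMs / dtMs)
  nSeg <- floor(length(x) / W)
  if (nSeg < 1) stop("trace shorter than one window")
  fs <- 1000 / dtMs
  nFreq <- floor(W / 2) + 1
  acc <- numeric(nFreq)
  for (s in seq_len(nSeg)) {
    seg <- x[((s - 1) * W + 1):(s * W)]
    ft <- fft(seg)
    pg <- (Mod(ft)^2) / (fs * W)
    acc <- acc + pg[seq_len(nFreq)]
  }
  data.frame(freq = (seq_len(nFreq) - 1) * fs / W, power = acc / nSeg)
}

#' Band power of a PSD
#'
#' @param psd data.frame from \code{\link{lfpPSD}}
#' @param band frequency band in Hz (default: gamma, 25--90)
#' @return mean power in the band
#' @export
bandPower <- function(psd, band = c(25, 90)) {
  inb <- psd$freq >= band[1] & psd$freq <= band[2]
  mean(psd$power[inb])
}

#' Trial-to-trial coefficient of variation
#'
#' CV (SD over mean across trials) of each neuron's spike count in a
#' window, plus a population summary.  Neurons with zero mean count are
#' excluded from the summary and reported separately.
#'
#' @param results list of \linkS4class{SimResult} or
#'   \linkS4class{SpikeRaster} from \code{\link{runTrials}}
#' @param window c(t0, t1), ms, within the trial duration
#' @param population "E", "I" or "all"
#' @param cluster optional (j, k) restriction
#' @return list with \code{cv} (per-neuron, NA where mean is 0),
#'   \code{median} (population median over defined CVs), \code{nZero}
#'   (neurons silent in all trials)
#' @export
trialCV <- function(results, window, population = "all", cluster = NULL) {
  stopifnot(length(results) >= 2)
  rr <- lapply(results, function(x) if (is(x, "SimResult")) x@raster else x)
  g <- rr[[1]]@geometry
  if (window[1] < 0 || window[2] > rr[[1]]@duration || window[1] >= window[2])
    stop("window outside the trial duration")
  nAll <- nNeurons(g)
  cnt <- sapply(rr, function(x) {
    sp <- x@spikes
    keep <- sp$t >= window[1] & sp$t < window[2]
    if (population != "all") keep <- keep & sp$Q == population
    if (!is.null(cluster))
      keep <- keep & sp$j == cluster[1] & sp$k == cluster[2]
    tabulate(sp$id[keep], nbins = nAll)
  })
  mu <- rowMeans(cnt)
  sdv <- apply(cnt, 1, sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  # restrict to neurons belonging to the selection
  sel <- rep(TRUE, nAll)
  nt <- makeNeuronTable(g)
  if (population != "all") sel <- sel & nt$type == population
  if (!is.null(cluster))
    sel <- sel & nt$j == cluster[1] & nt$k == cluster[2]
  cv <- cv[sel]; mu <- mu[sel]
  list(cv = cv, median = median(cv[mu > 0], na.rm = TRUE),
       nZero = sum(mu == 0))
}

#' Per-condition firing rates with MFE decomposition
#'
#' Time-averaged per-neuron rates in a chosen (center) cluster for each of a
#' set of runs, with the I-population rate split into MFE-spike and
#' non-MFE-spike rates by the 95 % rule.  The decomposition is an exact
#' partition: MFE + nonMFE = total.
#'
#' @param runs named list of \linkS4class{SimResult} /
#'   \linkS4class{SpikeRaster} (names label the conditions, e.g. the number
#'   of stimulated clusters)
#' @param cluster (j, k) of the analyzed cluster
#' @param binMs bin width for the 95 % rule, ms
#' @param burnIn initial ms excluded from the rates
#' @param percentile percentile of the binomial null
#' @return data.frame, one row per condition: \code{condition}, \code{rateE},
#'   \code{rateI}, \code{rateI_mfe}, \code{rateI_nonmfe}, \code{rateE_mfe},
#'   \code{rateE_nonmfe}, \code{cutoffE}, \code{cutoffI}
#' @export
rateCurves <- function(runs, cluster = c(1, 1), binMs = 1, burnIn = 500,
                       percentile = 0.95) {
  rr <- lapply(runs, function(x) if (is(x, "SimResult")) x@raster else x)
  g <- rr[[1]]@geometry
  for (x in rr) if (!identical(nNeurons(x@geometry), nNeurons(g)))
    stop("runs must share one geometry")
  rows <- lapply(seq_along(rr), function(z) {
    x <- rr[[z]]
    dur <- x@duration - burnIn
    stopifnot(dur > 0)
    sp <- x@spikes
    keep <- sp$t >= burnIn & sp$j == cluster[1] & sp$k == cluster[2]
    sub <- new("SpikeRaster",
               spikes = transform(sp[keep, ], t = t - burnIn),
               duration = dur, geometry = x@geometry, seed = x@seed)
    cnt <- binSpikes(sub, binMs)
    cnE <- sprintf("E.%d.%d", cluster[1], cluster[2])
    cnI <- sprintf("I.%d.%d", cluster[1], cluster[2])
    res <- list(condition = names(runs)[z])
    for (QQ in c("E", "I")) {
      cn <- if (QQ == "E") cnE else cnI
      nPop <- if (QQ == "E") g@nE else g@nI
      tot <- sum(cnt[, cn])
      rate <- tot / nPop / dur * 1000
      cut <- mfeCutoff(nPop, rate, binMs, percentile)
      mfeSpk <- sum(cnt[cnt[, cn] > cut, cn])
      res[[paste0("rate", QQ)]] <- rate
      res[[paste0("rate", QQ, "_mfe")]] <- mfeSpk / nPop / dur * 1000
      res[[paste0("rate", QQ, "_nonmfe")]] <- (tot - mfeSpk) / nPop / dur * 1000
      res[[paste0("cutoff", QQ)]] <- cut
    }
    as.data.frame(res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("condition", "rateE", "rateI", "rateI_mfe", "rateI_nonmfe",
          "rateE_mfe", "rateE_nonmfe", "cutoffE", "cutoffI")]
}

#' Background orientation-pattern episodes
#'
#' Operationalizes "sustained activity patterns" in background: the summed
#' E activity of each orientation is smoothed with a moving average; an
#' episode is a maximal run in which one orientation's smoothed activity is
#' the largest and exceeds the runner-up by at least \code{margin} (ratio),
#' lasting at least \code{minDur}.  The episode-duration distribution
#' summarizes the persistence timescale of the background patterns.  This
#' operationalization is a declared convention of the package.
#'
#' @param x a \linkS4class{SpikeRaster} or \linkS4class{SimResult}
#' @param binMs activity bin, ms
#' @param smoothMs moving-average window, ms
#' @param margin dominance ratio over the runner-up
#' @param minDur minimum episode duration, ms
#' @param burnIn initial ms excluded
#' @return list with \code{episodes} (data.frame: orientation, start, end,
#'   duration) and \code{tauPersist} (median duration, NA when no episodes)
#' @export
backgroundEpisodes <- function(x, binMs = 1, smoothMs = 25, margin = 1.5,
                               minDur = 25, burnIn = 500) {
  if (is(x, "SimResult")) x <- x@raster
  g <- x@geometry
  J <- g@nOrientations
  sp <- x@spikes
  keep <- sp$t >= burnIn & sp$Q == "E"
  nBin <- ceiling((x@duration - burnIn) / binMs)
  act <- matrix(0, nBin, J)
  if (any(keep)) {
    bin <- pmin(floor((sp$t[keep] - burnIn) / binMs), nBin - 1L) + 1L
    for (jj in seq_len(J)) {
      sel <- sp$j[keep] == jj
      if (any(sel))
        act[, jj] <- tabulate(bin[sel], nbins = nBin)
    }
  }
  w <- max(1L, round(smoothMs / binMs))
  kern <- rep(1 / w, w)
  sm <- apply(act, 2, function(v) as.numeric(stats::filter(v, kern,
                                                           sides = 2)))
  sm[is.na(sm)] <- 0
  top <- max.col(sm, ties.method = "first")
  topVal <- sm[cbind(seq_len(nBin), top)]
  runner <- apply(sm, 1, function(v) sort(v, decreasing = TRUE)[2])
  dominant <- topVal > margin * runner & topVal > 0
  lab <- ifelse(dominant, top, 0L)
  r <- rle(lab)
  ends <- cumsum(r$lengths); beg <- ends - r$lengths + 1L
  keepE <- which(r$values > 0 & r$lengths * binMs >= minDur)
  eps <- data.frame(orientation = r$values[keepE],
                    start = burnIn + (beg[keepE] - 1) * binMs,
                    end = burnIn + ends[keepE] * binMs)
  eps$duration <- eps$end - eps$start
  list(episodes = eps,
       tauPersist = if (nrow(eps)) median(eps$duration) else NA_real_)
}

#' Spectral coherence shift of population activity
#'
#' A simplified coherence estimator: Welch magnitude-squared coherence
#' between the summed spike counts of two random halves of a population.
#' Intended for comparing frequency bands before and after stimulus onset.
#'
#' @param x a \linkS4class{SpikeRaster} or \linkS4class{SimResult}
#' @param window c(t0, t1) ms
#' @param population "E" or "I"
#' @param binMs count bin, ms
#' @param windowMs Welch segment length, ms
#' @param seed seed for the random split
#' @return data.frame with \code{freq} (Hz) and \code{coherence}
#' @export
spikeCoherence <- function(x, window, population = "E", binMs = 1,
                           windowMs = 256, seed = 1) {
  if (is(x, "SimResult")) x <- x@raster
  sp <- x@spikes
  keep <- sp$t >= window[1] & sp$t < window[2] & sp$Q == population
  ids <- sort(unique(sp$id[keep]))
  half <- withSeed(seed, sample(ids, length(ids) %/% 2))
  nBin <- ceiling((window[2] - window[1]) / binMs)
  mkSeries <- function(idSet) {
    s <- keep & sp$id %in% idSet
    tabulate(pmin(floor((sp$t[s] - window[1]) / binMs), nBin - 1L) + 1L,
             nbins = nBin)
  }
  a <- mkSeries(half); b <- mkSeries(setdiff(ids, half))
  W <- round(windowMs / binMs)
  nSeg <- floor(nBin / W)
  if (nSeg < 2) stop("window too short for coherence segments")
  nFreq <- floor(W / 2) + 1
  Saa <- Sbb <- numeric(nFreq); Sab <- complex(nFreq)
  for (s in seq_len(nSeg)) {
    ia <- a[((s - 1) * W + 1):(s * W)]; ib <- b[((s - 1) * W + 1):(s * W)]
    fa <- fft(ia - mean(ia)); fb <- fft(ib - mean(ib))
    Saa <- Saa + Mod(fa[1:nFreq])^2
    Sbb <- Sbb + Mod(fb[1:nFreq])^2
    Sab <- Sab + fa[1:nFreq] * Conj(fb[1:nFreq])
  }
  coh <- Mod(Sab)^2 / pmax(Saa * Sbb, .Machine$double.eps)
  data.frame(freq = (seq_len(nFreq) - 1) * 1000 / (W * binMs),
             coherence = coh)
}
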