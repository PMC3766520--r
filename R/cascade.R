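# Exact resolution of one multiple-firing event (MFE).

#' Resolve a cascade of firings at a single instant
#'
#' Resolves the chain reaction set off when a neuron reaches threshold, in
#' the instantaneous fast-synapse limit.  Because every fast kernel is an
#' exponential with the same decay constant, the within-instant dynamics --
#' membrane equations driven only by the overlapping fast kernels of the
#' spikes already fired, leak and slow currents frozen -- have a closed-form
#' solution between firings once time is rescaled by the (vanishing) fast
#' timescale.  The resolver exploits this: it repeatedly finds the earliest
#' threshold crossing among all neurons in closed form, fires that neuron,
#' adds its outgoing fast weights to its targets' pending kernels, and
#' repeats until no further crossing occurs, then delivers all remaining
#' kernel area.  The fired set and firing order are therefore exactly those
#' of the conductance-based dynamics as the fast decay time goes to zero.
#'
#' Each neuron fires at most once per instant (the refractory period is
#' taken to dominate the fast timescale).  Slow-conductance increments
#' earned during the cascade are returned in \code{slowPending} and take
#' effect only after the instant; neurons refractory at the end of the
#' instant -- including every neuron that fired -- receive none.  If several
#' neurons sit at or above threshold when the instant opens, they all fire
#' at its opening and are ordered by voltage surplus, ties broken by a
#' seeded per-instant random permutation.
#'
#' @param V voltages of all neurons at the instant (initiator at/above
#'   threshold)
#' @param pop population tags, "E" or "I" (the sender's type selects the
#'   reversal its fast synapses pull toward)
#' @param Wfast fast weight matrix (receiver x sender), dense or dgCMatrix
#' @param Wslow optional slow weight matrix of the same shape
#' @param initiators indices of the neurons at/above threshold
#' @param params a \linkS4class{NeuronParams}
#' @param blocked logical vector, TRUE for refractory neurons
#' @param seed seed for the per-instant tie-break stream
#' @return a \linkS4class{CascadeResult}
#' @examples
#' W <- matrix(0, 2, 2); W[2, 1] <- 2  # strong E1 -> E2 synapse
#' r <- resolveCascade(c(1, 0.99), c("E", "E"), W, initiators = 1)
#' r@order  # both fire: the cascade recruited neuron 2
#' @export
resolveCascade <- function(V, pop, Wfast, Wslow = NULL, initiators,
                           params = neuronParams(),
                           blocked = rep(FALSE, length(V)), seed = 1L) {
  n <- length(V)
  stopifnot(length(pop) == n, all(pop %in% c("E", "I")))
  if (any(V[initiators] < params@VT))
    stop("all initiators must be at or above threshold")
  Wfast <- methods::as(methods::as(Matrix::Matrix(Wfast, sparse = TRUE),
                                   "CsparseMatrix"), "generalMatrix")
  if (any(Wfast@x < 0)) stop("weights must be >= 0")
  hasSlow <- !is.null(Wslow)
  if (hasSlow) {
    Wslow <- methods::as(methods::as(Matrix::Matrix(Wslow, sparse = TRUE),
                                     "CsparseMatrix"), "generalMatrix")
    if (!identical(Wfast@p, Wslow@p) || !identical(Wfast@i, Wslow@i)) {
      # align the two sparsity patterns on their union
      tf <- Matrix::summary(Wfast); ts <- Matrix::summary(Wslow)
      key <- unique(rbind(tf[, 1:2], ts[, 1:2]))
      kf <- match(paste(tf$i, tf$j), paste(key$i, key$j))
      ks <- match(paste(ts$i, ts$j), paste(key$i, key$j))
      xf <- numeric(nrow(key)); xf[kf] <- tf$x
      xs <- numeric(nrow(key)); xs[ks] <- ts$x
      Wfast <- Matrix::sparseMatrix(i = key$i, j = key$j, x = xf, dims = c(n, n))
      Wslow <- Matrix::sparseMatrix(i = key$i, j = key$j, x = xs, dims = c(n, n))
    }
  }

  # order simultaneous initiators: largest voltage surplus first,
  # random tie-break from a per-instant stream
  init <- as.integer(initiators)
  if (length(init) > 1) {
    perm <- withSeed(seed, sample.int(length(init)))
    init <- init[perm][order(V[init[perm]], decreasing = TRUE)]
  }

  out <- cpp_resolve_cascade(
    as.numeric(V), as.integer(pop == "I"),
    Wfast@p, Wfast@i, Wfast@x,
    if (hasSlow) Wslow@x else numeric(0),
    as.logical(blocked), init - 1L,
    list(VL = params@VL, VE = params@VE, VI = params@VI, VT = params@VT,
         Vreset = params@Vreset, tauV = params@tauV))

  fired <- out$fired + 1L
  new("CascadeResult",
      firedE = fired[pop[fired] == "E"],
      firedI = fired[pop[fired] == "I"],
      order = fired,
      Vpre = as.numeric(V), Vpost = out$V_post,
      slowPending = out$slow_pending)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
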