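# Construction and validation of the cluster / hypercolumn architecture.

#' Connectivity parameters
#'
#' Defaults follow the model's architecture: within-cluster connectivity is
#' ~20 % from excitatory and ~50 % from inhibitory presynaptic neurons
#' (I-neurons arborize more densely), connectivity across clusters of one
#' hypercolumn is half that within a cluster, and long-range connections
#' (same orientation, different hypercolumn, excitatory senders only) use
#' the same halved probability with separately controlled strengths.
#'
#' @param pFromE,pFromI within-cluster connection probabilities by
#'   presynaptic type
#' @param crossClusterFactor probability multiplier across clusters within a
#'   hypercolumn
#' @param pLongRange probability across hypercolumns; defaults to the
#'   cross-cluster value \code{crossClusterFactor * pFromE}
#' @param sFast 2x2 local fast strengths (rows receiver E,I; cols sender E,I)
#' @param sSlow,lFast,lSlow length-2 strengths (receiver E, I), E senders
#' @param delay horizontal synaptic delay in ms for long-range connections
#' @return a validated \linkS4class{ConnectivityParams}
#' @export
connectivityParams <- function(pFromE = 0.20, pFromI = 0.50,
                               crossClusterFactor = 0.5,
                               pLongRange = crossClusterFactor * pFromE,
                               sFast = matrix(c(0.1, 0.1, 0.2, 0.2), 2, 2,
                                              dimnames = list(c("E", "I"),
                                                              c("E", "I"))),
                               sSlow = c(E = 0.3, I = 0.3),
                               lFast = c(E = 0.05, I = 0.1),
                               lSlow = c(E = 0.1, I = 0.2),
                               delay = 0) {
  new("ConnectivityParams", pFromE = pFromE, pFromI = pFromI,
      crossClusterFactor = crossClusterFactor, pLongRange = pLongRange,
      sFast = sFast, sSlow = as.numeric(sSlow), lFast = as.numeric(lFast),
      lSlow = as.numeric(lSlow), delay = delay)
}

# neuron table for a geometry: cluster-major, E block then I block
makeNeuronTable <- function(geom) {
  J <- geom@nOrientations; K <- geom@nHypercolumns
  nPer <- geom@nE + geom@nI
  cluster <- rep(seq_len(J * K), each = nPer)
  k <- (cluster - 1L) %/% J + 1L
  j <- (cluster - 1L) %% J + 1L
  type <- rep(rep(c("E", "I"), c(geom@nE, geom@nI)), J * K)
  l <- rep(c(seq_len(geom@nE), seq_len(geom@nI)), J * K)
  data.frame(id = seq_along(cluster), type = type, j = j, k = k, l = l,
             cluster = cluster)
}

#' Build a cluster / hypercolumn network
#'
#' Connects every ordered (sender, receiver) pair independently with the
#' probability implied by its class -- sender type and the same-cluster /
#' same-hypercolumn / same-orientation indicators -- and gives connected
#' pairs the class's fast and slow weights.  No self-connections.  Across
#' hypercolumns only excitatory neurons send, and only to clusters of the
#' same orientation.  Slow weights are zero for inhibitory senders
#' everywhere.  The build is reproducible given the seed.
#'
#' @param geometry a \linkS4class{NetworkGeometry}
#' @param connectivity a \linkS4class{ConnectivityParams}
#' @param seed build seed
#' @return a \linkS4class{CortexNetwork}
#' @examples
#' net <- buildNetwork(networkGeometry(1, 1, 20, 20), seed = 1)
#' nNeurons(net)
#' @export
buildNetwork <- function(geometry = networkGeometry(),
                         connectivity = connectivityParams(), seed = 1) {
  validObject(geometry); validObject(connectivity)
  nt <- makeNeuronTable(geometry)
  n <- nrow(nt)
  J <- geometry@nOrientations; K <- geometry@nHypercolumns
  nC <- J * K; nPer <- geometry@nE + geometry@nI
  cv <- connectivity

  # per-cluster index helpers
  clusterStart <- (seq_len(nC) - 1L) * nPer
  cj <- (seq_len(nC) - 1L) %% J + 1L
  ck <- (seq_len(nC) - 1L) %/% J + 1L

  sendL <- list(); rcvL <- list(); relL <- list()
  withSeed(seed, {
    for (sc in seq_len(nC)) for (rc in seq_len(nC)) for (st in c("E", "I")) {
      if (sc == rc) rel <- "local"
      else if (ck[sc] == ck[rc]) rel <- "cross"
      else if (cj[sc] == cj[rc]) rel <- "long"
      else next
      if (rel == "long" && st == "I") next
      p <- switch(rel,
                  local = if (st == "E") cv@pFromE else cv@pFromI,
                  cross = cv@crossClusterFactor *
                    (if (st == "E") cv@pFromE else cv@pFromI),
                  long  = cv@pLongRange)
      if (p <= 0) next
      senders <- clusterStart[sc] +
        (if (st == "E") seq_len(geometry@nE)
         else geometry@nE + seq_len(geometry@nI))
      nS <- length(senders); nR <- nPer
      hit <- which(runif(nS * nR) < p)
      if (!length(hit)) next
      sIdx <- senders[(hit - 1L) %/% nR + 1L]
      rIdx <- clusterStart[rc] + (hit - 1L) %% nR + 1L
      keep <- sIdx != rIdx
      sendL[[length(sendL) + 1L]] <- sIdx[keep]
      rcvL[[length(rcvL) + 1L]] <- rIdx[keep]
      relL[[length(relL) + 1L]] <- rep(rel, sum(keep))
    }
  })
  send <- unlist(sendL, use.names = FALSE)
  rcv <- unlist(rcvL, use.names = FALSE)
  rel <- unlist(relL, use.names = FALSE)

  sType <- nt$type[send]; rType <- nt$type[rcv]
  ri <- ifelse(rType == "E", 1L, 2L); si <- ifelse(sType == "E", 1L, 2L)
  wf <- ifelse(rel == "long", cv@lFast[ri], cv@sFast[cbind(ri, si)])
  ws <- ifelse(sType == "I", 0,
               ifelse(rel == "long", cv@lSlow[ri], cv@sSlow[ri]))

  Wfast <- Matrix::sparseMatrix(i = rcv, j = send, x = wf, dims = c(n, n))
  Wslow <- Matrix::sparseMatrix(i = rcv, j = send, x = ws, dims = c(n, n))
  new("CortexNetwork", geometry = geometry, connectivity = connectivity,
      neurons = nt, Wfast = Wfast, Wslow = Wslow, seed = seed)
}

#' Validate a network's architectural invariants
#'
#' Asserts the zero-structure (no slow output from I neurons, no I output
#' across hypercolumns, long-range connections only between same-orientation
#' clusters, no self-connections) and class-wise weight homogeneity, and
#' reports the empirical connection fraction of every pair class against its
#' configured probability.
#'
#' @param network a \linkS4class{CortexNetwork}
#' @return a list with \code{ok} (logical), \code{failures} (character) and
#'   \code{report} (data.frame of per-class empirical connection fractions,
#'   configured probabilities and binomial standard errors)
#' @export
validateNetwork <- function(network) {
  nt <- network@neurons
  cv <- network@connectivity
  geom <- network@geometry
  failures <- character()

  tf <- Matrix::summary(network@Wfast)   # i receiver, j sender, x weight
  ts <- Matrix::summary(network@Wslow)
  if (!identical(tf$i, ts$i) || !identical(tf$j, ts$j))
    failures <- c(failures, "fast/slow adjacency patterns differ")

  sType <- nt$type[tf$j]; rType <- nt$type[tf$i]
  sameK <- nt$k[tf$j] == nt$k[tf$i]
  sameJ <- nt$j[tf$j] == nt$j[tf$i]
  sameC <- nt$cluster[tf$j] == nt$cluster[tf$i]

  if (any(tf$i == tf$j)) failures <- c(failures, "self-connections present")
  if (any(sType == "I" & !sameK))
    failures <- c(failures, "I neuron sends across hypercolumns")
  if (any(!sameK & !sameJ))
    failures <- c(failures, "long-range connection between unlike orientations")
  if (any(ts$x[sType == "I"] != 0))
    failures <- c(failures, "nonzero slow weight from an I sender")

  rel <- ifelse(sameC, "local", ifelse(sameK, "cross", "long"))
  cls <- paste(rel, "from", sType, "to", rType)
  for (cl in unique(cls)) {
    w <- tf$x[cls == cl]
    if (length(unique(w)) > 1L)
      failures <- c(failures,
                    sprintf("heterogeneous fast weights in class '%s'", cl))
    wsl <- ts$x[cls == cl]
    if (length(unique(wsl)) > 1L)
      failures <- c(failures,
                    sprintf("heterogeneous slow weights in class '%s'", cl))
  }

  # empirical connection fractions per (relation, sender type)
  nC <- nClusters(geom); nPer <- geom@nE + geom@nI
  K <- geom@nHypercolumns; J <- geom@nOrientations
  nPairs <- function(relname, st) {
    nS <- if (st == "E") geom@nE else geom@nI
    switch(relname,
           local = nC * nS * (nPer - 1L),
           cross = nC * (J - 1L) * nS * nPer,
           long  = if (st == "E") nC * (K - 1L) * nS * nPer else 0)
  }
  rep_rows <- list()
  for (relname in c("local", "cross", "long")) for (st in c("E", "I")) {
    np <- nPairs(relname, st)
    if (np == 0) next
    ne <- sum(rel == relname & sType == st)
    p0 <- switch(relname,
                 local = if (st == "E") cv@pFromE else cv@pFromI,
                 cross = cv@crossClusterFactor *
                   (if (st == "E") cv@pFromE else cv@pFromI),
                 long  = cv@pLongRange)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      relation = relname, sender = st, pairs = np, edges = ne,
      fraction = ne / np, configured = p0,
      se = sqrt(p0 * (1 - p0) / np))
  }
  report <- do.call(rbind, rep_rows)
  dev <- abs(report$fraction - report$configured) / report$se
  bad <- which(report$configured > 0 & dev > 6)
  if (length(bad))
    failures <- c(failures, sprintf(
      "connection fraction for %s-from-%s deviates %.1f SE from %.3f",
      report$relation[bad], report$sender[bad], dev[bad],
      report$configured[bad]))

  list(ok = length(failures) == 0L, failures = failures, report = report)
}

#' Within-cluster connection fractions by presynaptic type
#'
#' Fraction of ordered within-cluster (sender, receiver) pairs that are
#' connected, split by the sender's type.
#'
#' @param network a \linkS4class{CortexNetwork}
#' @return named numeric vector with elements \code{E} and \code{I}
#' @export
localConnectionFractions <- function(network) {
  rp <- validateNetwork(network)$report
  loc <- rp[rp$relation == "local", ]
  stats::setNames(loc$fraction, loc$sender)[c("E", "I")]
}

#' Write / read a network as plain-text files
#'
#' Serializes a network to a documented sparse-triplet container: a neuron
#' table (\code{<prefix>-neurons.tsv}), an edge list with fast and slow
#' weights (\code{<prefix>-edges.tsv}, full precision) and a JSON metadata
#' file (\code{<prefix>-meta.json}).  The round trip is bit-exact.
#'
#' @param network a \linkS4class{CortexNetwork}
#' @param prefix path prefix for the three files
#' @return \code{writeNetwork} returns the prefix invisibly;
#'   \code{readNetwork} returns the reconstructed
#'   \linkS4class{CortexNetwork}
#' @export
writeNetwork <- function(network, prefix) {
  nt <- network@neurons
  write.table(nt, paste0(prefix, "-neurons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tf <- Matrix::summary(network@Wfast); ts <- Matrix::summary(network@Wslow)
  stopifnot(identical(tf$i, ts$i), identical(tf$j, ts$j))
  ed <- data.frame(sender = tf$j, receiver = tf$i,
                   w_fast = sprintf("%.17g", tf$x),
                   w_slow = sprintf("%.17g", ts$x))
  write.table(ed, paste0(prefix, "-edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- network@geometry; cv <- network@connectivity
  num <- function(x) sprintf("%.17g", as.numeric(x))  # bit-exact round trip
  meta <- list(
    geometry = list(nHypercolumns = g@nHypercolumns,
                    nOrientations = g@nOrientations, nE = g@nE, nI = g@nI),
    connectivity = list(pFromE = num(cv@pFromE), pFromI = num(cv@pFromI),
                        crossClusterFactor = num(cv@crossClusterFactor),
                        pLongRange = num(cv@pLongRange),
                        sFast = num(cv@sFast), sSlow = num(cv@sSlow),
                        lFast = num(cv@lFast), lSlow = num(cv@lSlow),
                        delay = num(cv@delay)),
    seed = num(network@seed))
  jsonlite::write_json(meta, paste0(prefix, "-meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(prefix) {
  nt <- read.table(paste0(prefix, "-neurons.tsv"), sep = "\t", header = TRUE,
                   colClasses = c("integer", "character", "integer",
                                  "integer", "integer", "integer"))
  ed <- read.table(paste0(prefix, "-edges.tsv"), sep = "\t", header = TRUE,
                   colClasses = c("integer", "integer", "character",
                                  "character"))
  meta <- jsonlite::read_json(paste0(prefix, "-meta.json"),
                              simplifyVector = TRUE)
  g <- networkGeometry(meta$geometry$nHypercolumns,
                       meta$geometry$nOrientations,
                       meta$geometry$nE, meta$geometry$nI)
  mc <- lapply(meta$connectivity, as.numeric)
  cv <- connectivityParams(
    pFromE = mc$pFromE, pFromI = mc$pFromI,
    crossClusterFactor = mc$crossClusterFactor, pLongRange = mc$pLongRange,
    sFast = matrix(mc$sFast, 2, 2,
                   dimnames = list(c("E", "I"), c("E", "I"))),
    sSlow = mc$sSlow, lFast = mc$lFast, lSlow = mc$lSlow, delay = mc$delay)
  n <- nrow(nt)
  Wfast <- Matrix::sparseMatrix(i = ed$receiver, j = ed$sender,
                                x = as.numeric(ed$w_fast), dims = c(n, n))
  Wslow <- Matrix::sparseMatrix(i = ed$receiver, j = ed$sender,
                                x = as.numeric(ed$w_slow), dims = c(n, n))
  new("CortexNetwork", geometry = g, connectivity = cv, neurons = nt,
      Wfast = Wfast, Wslow = Wslow, seed = as.numeric(meta$seed))
}
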