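# Named parameter regimes: structured-text storage with checksums.

regimeToList <- function(regime) {
  g <- regime@geometry; cv <- regime@connectivity; dr <- regime@drive
  kn <- regime@kernels; np <- regime@neuron
  list(
    name = regime@name,
    notes = regime@notes,
    geometry = list(nHypercolumns = g@nHypercolumns,
                    nOrientations = g@nOrientations, nE = g@nE, nI = g@nI),
    neuron = list(VL = np@VL, VE = np@VE, VI = np@VI, VT = np@VT,
                  Vreset = np@Vreset, tauV = np@tauV, tauRef = np@tauRef),
    kernels = list(tauSlow = kn@tauSlow, tauFastE = kn@tauFastE,
                   tauFastI = kn@tauFastI),
    connectivity = list(
      pFromE = cv@pFromE, pFromI = cv@pFromI,
      crossClusterFactor = cv@crossClusterFactor,
      pLongRange = cv@pLongRange,
      sFast = list(EE = cv@sFast[1, 1], EI = cv@sFast[1, 2],
                   IE = cv@sFast[2, 1], II = cv@sFast[2, 2]),
      sSlow = list(E = cv@sSlow[1], I = cv@sSlow[2]),
      lFast = list(E = cv@lFast[1], I = cv@lFast[2]),
      lSlow = list(E = cv@lSlow[1], I = cv@lSlow[2]),
      delay = cv@delay),
    drive = list(etaBkgE = dr@etaBkgE, etaBkgI = dr@etaBkgI,
                 sDriveE = dr@sDriveE, sDriveI = dr@sDriveI),
    checklist = as.list(regime@checklist))
}

regimeFromList <- function(x) {
  cvl <- x$connectivity
  cv <- connectivityParams(
    pFromE = cvl$pFromE, pFromI = cvl$pFromI,
    crossClusterFactor = cvl$crossClusterFactor,
    pLongRange = cvl$pLongRange,
    sFast = matrix(c(cvl$sFast$EE, cvl$sFast$IE, cvl$sFast$EI,
                     cvl$sFast$II), 2, 2,
                   dimnames = list(c("E", "I"), c("E", "I"))),
    sSlow = c(E = cvl$sSlow$E, I = cvl$sSlow$I),
    lFast = c(E = cvl$lFast$E, I = cvl$lFast$I),
    lSlow = c(E = cvl$lSlow$E, I = cvl$lSlow$I),
    delay = cvl$delay)
  chk <- unlist(x$checklist)
  if (is.null(chk)) chk <- logical(0)
  new("Regime", name = x$name,
      geometry = networkGeometry(x$geometry$nHypercolumns,
                                 x$geometry$nOrientations,
                                 x$geometry$nE, x$geometry$nI),
      connectivity = cv,
      drive = driveParams(x$drive$etaBkgE, x$drive$etaBkgI,
                          x$drive$sDriveE, x$drive$sDriveI),
      kernels = synapticKernels(x$kernels$tauSlow, x$kernels$tauFastE,
                                x$kernels$tauFastI),
      neuron = neuronParams(x$neuron$VL, x$neuron$VE, x$neuron$VI,
                            x$neuron$VT, x$neuron$Vreset, x$neuron$tauV,
                            x$neuron$tauRef),
      notes = as.character(x$notes), checklist = chk)
}

regimeChecksum <- function(lst) {
  lst$checksum <- NULL
  canon <- paste(deparse(lst[order(names(lst))], control = "all"),
                 collapse = "\n")
  tf <- tempfile()
  writeLines(canon, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Write / load a regime as structured text
#'
#' Regimes are stored as YAML with an md5 checksum of their canonical
#' parameter serialization; \code{loadRegime} verifies it.
#'
#' @param regime a \linkS4class{Regime}
#' @param file path (\code{writeRegime}); path or installed regime name
#'   (\code{loadRegime})
#' @return the path / the \linkS4class{Regime}
#' @export
writeRegime <- function(regime, file) {
  lst <- regimeToList(regime)
  lst$checksum <- regimeChecksum(lst)
  yaml::write_yaml(lst, file, precision = 17)
  invisible(file)
}

#' @rdname writeRegime
#' @export
loadRegime <- function(file) {
  if (!file.exists(file)) {
    cand <- system.file("extdata", "regimes", paste0(file, ".yaml"),
                        package = "MFEsim")
    if (!nzchar(cand)) stop("regime not found: ", file)
    file <- cand
  }
  lst <- yaml::read_yaml(file)
  ck <- lst$checksum
  lst$checksum <- NULL
  if (!is.null(ck) && !identical(unname(regimeChecksum(lst)), ck))
    stop("regime checksum mismatch in ", file)
  regimeFromList(lst)
}

#' Installed regime names
#' @return character vector of regimes shipped with the package
#' @export
listRegimes <- function() {
  dir <- system.file("extdata", "regimes", package = "MFEsim")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' The package's tuned full-network regime
#'
#' The model's reference coupling values are not publicly available; this
#' regime was tuned by the package authors against the qualitative
#' benchmark checklist (plausible background rates, 50--500 ms
#' background patterns, iso-oriented surround suppression of E firing,
#' gamma-band elevation under drive, trial-variability drop at onset).
#'
#' @return a \linkS4class{Regime}
#' @export
defaultRegime <- function() loadRegime("mfe-default")

#' Single-cluster MFE regime
#'
#' One cluster of 128 E + 128 I neurons in a dynamical regime chosen to
#' exhibit clear multiple-firing events, for cascade-level experiments.
#'
#' @return a \linkS4class{Regime}
#' @export
singleClusterRegime <- function() loadRegime("mfe-single")

#' Build the network of a regime
#'
#' @param regime a \linkS4class{Regime}
#' @param seed build seed
#' @return a \linkS4class{CortexNetwork}
#' @export
regimeNetwork <- function(regime, seed = 1) {
  buildNetwork(regime@geometry, regime@connectivity, seed)
}
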