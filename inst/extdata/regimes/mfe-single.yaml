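name: mfe-single
notes: 'Single cluster in a clearly MFE-dominated regime (tuned in-house): barrages
  of correlated E/I firing separated by recharge lulls.'
geometry:
  nHypercolumns: 1
  nOrientations: 1
  nE: 128
  nI: 128
neuron:
  VL: 0.0
  VE: 4.66666666666666696
  VI: -0.66666666666666663
  VT: 1.0
  Vreset: 0.0
  tauV: 20.0
  tauRef: 1.0
kernels:
  tauSlow: 128.0
  tauFastE: 0.0
  tauFastI: 0.0
connectivity:
  pFromE: 0.20000000000000001
  pFromI: 0.5
  crossClusterFactor: 0.5
  pLongRange: 0.10000000000000001
  sFast:
    EE: 1.0
    EI: 2.0
    IE: 0.80000000000000004
    II: 1.0
  sSlow:
    E: 0.5
    I: 0.5
  lFast:
    E: 0.0
    I: 0.0
  lSlow:
    E: 0.0
    I: 0.0
  delay: 0.0
drive:
  etaBkgE: 375.0
  etaBkgI: 375.0
  sDriveE: 0.5
  sDriveI: 0.5
checklist: []
checksum: a69f76c8d6d5e8ea829961f88dbb5fae
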