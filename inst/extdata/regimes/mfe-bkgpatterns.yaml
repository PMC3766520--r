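name: mfe-bkgpatterns
notes: 'Background-pattern variant: iso-orientation clusters co-activate in episodes
  of tens to hundreds of ms with positive same-orientation and negative cross-orientation
  covariance. Not suitable for surround-suppression experiments: sustained full-row
  drive destabilizes this parameter point.'
geometry:
  nHypercolumns: 8
  nOrientations: 3
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
    EI: 1.19999999999999996
    IE: 1.0
    II: 0.69999999999999996
  sSlow:
    E: 0.5
    I: 0.5
  lFast:
    E: 0.20000000000000001
    I: 0.5
  lSlow:
    E: 0.72999999999999998
    I: 0.5
  delay: 0.0
drive:
  etaBkgE: 300.0
  etaBkgI: 300.0
  sDriveE: 0.62
  sDriveI: 0.34999999999999998
checklist: []
checksum: 1c6a20fb438a3094cad8a720f1968919
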