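name: mfe-default
notes: Tuned by the package authors to the qualitative benchmark checklist; reference
  coupling values are not publicly available and were not used. Drive ratio S_drive_E/S_EE
  = 0.62 (the 'approximately one half' constraint). Long-range coupling favors I targets,
  giving robust iso-oriented surround suppression; this choice trades away sustained
  background orientation patterns (see mfe-bkgpatterns).
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
    E: 0.34999999999999998
    I: 0.80000000000000004
  lSlow:
    E: 0.45000000000000001
    I: 0.40000000000000002
  delay: 0.0
drive:
  etaBkgE: 300.0
  etaBkgI: 300.0
  sDriveE: 0.62
  sDriveI: 0.34999999999999998
checklist:
  background_rates_plausible: yes
  episodes_50_500ms: no
  surround_suppression_E: yes
  gamma_elevated_under_drive: no
  cv_drop_at_onset: yes
checksum: 7602f9398f44ee5b278d214a3fc20405
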