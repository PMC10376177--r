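# Spectrophotometric assay parameters keyed by substrate.
# epsilon in mM^-1 cm^-1 unless epsilon_unit: M.
# volume_ml / enzyme_mg are per-experiment and must be supplied as overrides.
ABTS:
  epsilon: 31.1
  wavelength: 414
  path_cm: 1
  volume_ml: 1
  enzyme_mg: 0.01
guaiacol:
  epsilon: 26.6
  wavelength: 470
  path_cm: 1
  volume_ml: 1
  enzyme_mg: 0.01
L-DOPA:
  epsilon: 3.6
  wavelength: 470
  path_cm: 1
  volume_ml: 1
  enzyme_mg: 0.01
MnSO4:
  epsilon: 6.5
  wavelength: 238
  path_cm: 1
  volume_ml: 1
  enzyme_mg: 0.01
H2O2:
  epsilon: 43.6
  epsilon_unit: M
  wavelength: 240
  path_cm: 1
  volume_ml: 3
  enzyme_mg: 0.01
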