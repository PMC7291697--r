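# Provenance of the packaged chromophore absorption tables
kind: synthetic parametric reconstruction
description: >
  Specific absorption curves for HbO2, Hb (per g/l of hemoglobin,
  molar mass 64500 g/mol) and bulk absorption of pure water and pure
  lipid (per unit volume fraction), tabulated at 2 nm over 450-1600 nm.
  The curves are monotone-Hermite interpolations of hand-set anchor
  points reproducing the canonical literature band structure
  (hemoglobin visible Q-bands, water 970/1200/1450 nm and lipid
  930/1210/1400 nm overtones). They are NOT digitized measurements;
  use only for simulation and self-consistent inversion.
units:
  wavelength_nm: nm
  hbo2: cm^-1 per (g/l)
  hb: cm^-1 per (g/l)
  water: cm^-1 per unit volume fraction
  fat: cm^-1 per unit volume fraction
support_nm: [450, 1600]
generated_by: scripts/make_chromophore_tables.R
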