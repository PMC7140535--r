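# Example scenario: a short desk-scale course of the reference
# relapsing-remitting parameter set under IFN-beta1a.
label: reference-ms-ifnb1a-desk
horizon_years: 0.5
seed: 11
scale: 0.2
lattice_side: 8
disease:
  odc_apoptosis_prob: 5.0e-4
  central_tolerance_impairment: 0.6
  peripheral_tolerance_impairment: 0.6
white_matter:
  volume_mm3: 0.6
  mri_loss_threshold: 10000
treatments:
  - drug: ifnb1a
    start_day: 0
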