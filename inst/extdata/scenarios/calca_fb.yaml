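# FastBlue tracer + CGRP (Calca) reporter, spared nerve transection:
# partial loss of the peptidergic class.
scenario_id: calca_fb
n_neurons: 8000
semi_axes: [250.0, 200.0, 350.0]
territory_fractions: {tibial: 0.35, peroneal: 0.45, sural: 0.20}
subpopulations:
  - {name: cgrp,  fraction: 0.481, soma_area_mean: 380.0, soma_area_sd: 150.0, nucleus_ratio: 0.45, markers: [YFP]}
  - {name: other, fraction: 0.519, soma_area_mean: 500.0, soma_area_sd: 200.0, nucleus_ratio: 0.45, markers: []}
injury:
  axotomized_territories: [tibial, peroneal]
calibration:
  marker_subpop: cgrp
  p_contra: 0.481
  p_ipsi: 0.343
  base_survival: {7: 1.0, 14: 0.60, 28: 0.50}
labels:
  - {label: YFP, target: marker, marker: YFP, sensitivity: 1.0, false_positive: 0.0}
  - {label: FB,  target: territory, territory: tibial, sensitivity: 0.97, false_positive: 0.0}
sectioning: {thickness: 30.0, dz: 3.0, n_slides: 5, axial_shrinkage: 0.85, thickness_noise: 0.10}
timepoints: [28]
readouts: [colabel]
colabel: {reference: FB, marker: YFP}
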