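# FastBlue tracer + Trpm8 reporter, spared nerve transection: partial loss
# of the cold-sensitive class.
scenario_id: trpm8_fb
n_neurons: 8000
semi_axes: [250.0, 200.0, 350.0]
territory_fractions: {tibial: 0.35, peroneal: 0.45, sural: 0.20}
subpopulations:
  - {name: trpm8, fraction: 0.083, soma_area_mean: 300.0, soma_area_sd: 110.0, nucleus_ratio: 0.45, markers: [tdTom]}
  - {name: other, fraction: 0.917, soma_area_mean: 450.0, soma_area_sd: 180.0, nucleus_ratio: 0.45, markers: []}
injury:
  axotomized_territories: [tibial, peroneal]
calibration:
  marker_subpop: trpm8
  p_contra: 0.083
  p_ipsi: 0.042
  base_survival: {7: 1.0, 14: 0.60, 28: 0.50}
labels:
  - {label: tdTom, target: marker, marker: tdTom, sensitivity: 1.0, false_positive: 0.0}
  - {label: FB,    target: territory, territory: tibial, sensitivity: 0.97, false_positive: 0.0}
sectioning: {thickness: 30.0, dz: 3.0, n_slides: 5, axial_shrinkage: 0.85, thickness_noise: 0.10}
timepoints: [28]
readouts: [colabel]
colabel: {reference: FB, marker: tdTom}
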