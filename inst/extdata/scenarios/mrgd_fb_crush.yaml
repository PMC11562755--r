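# FastBlue tracer + permanent Mrgprd reporter, spared nerve crush
# (regeneration-permissive): partial loss of the marker class.
scenario_id: mrgd_fb_crush
n_neurons: 8000
semi_axes: [250.0, 200.0, 350.0]
territory_fractions: {tibial: 0.35, peroneal: 0.45, sural: 0.20}
subpopulations:
  - {name: mrgprd, fraction: 0.15, soma_area_mean: 361.0, soma_area_sd: 138.0, nucleus_ratio: 0.45, markers: [YFP]}
  - {name: other,  fraction: 0.85, soma_area_mean: 450.0, soma_area_sd: 180.0, nucleus_ratio: 0.45, markers: []}
injury:
  axotomized_territories: [tibial, peroneal]
calibration:
  marker_subpop: mrgprd
  p_contra: 0.15
  p_ipsi: 0.060
  base_survival: {7: 1.0, 14: 0.60, 28: 0.50}
labels:
  - {label: YFP, target: marker, marker: YFP, sensitivity: 1.0, false_positive: 0.0}
  - {label: FB,  target: territory, territory: tibial, sensitivity: 0.97, false_positive: 0.0}
sectioning: {thickness: 30.0, dz: 3.0, n_slides: 5, axial_shrinkage: 0.85, thickness_noise: 0.10}
timepoints: [28]
readouts: [colabel]
colabel: {reference: FB, marker: YFP}
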