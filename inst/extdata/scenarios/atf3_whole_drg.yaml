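# Whole-DRG transection scenario: injury-reporter (GFP) switching in
# axotomized neurons, constitutive tdTomato in intact neurons, FastBlue
# tracer in the tibial territory. Subpopulation survival schedules are
# composition-weighted so whole-DRG axotomized survival is 1.00 / 0.45 /
# 0.41 / 0.39 at 7 / 14 / 28 / 56 days (~61% loss of reporter-positive
# neurons between 1 and 8 weeks, i.e. total neuron number about halved),
# with loss concentrated in small-diameter subpopulations.
scenario_id: atf3_whole_drg
n_neurons: 8000
semi_axes: [250.0, 200.0, 350.0]
territory_fractions: {tibial: 0.35, peroneal: 0.45, sural: 0.20}
subpopulations:
  - {name: mrgprd,     fraction: 0.30, soma_area_mean: 361.0, soma_area_sd: 138.0, nucleus_ratio: 0.45, markers: [Mrgprd]}
  - {name: cgrp,       fraction: 0.30, soma_area_mean: 380.0, soma_area_sd: 150.0, nucleus_ratio: 0.45, markers: [CGRP]}
  - {name: trpm8,      fraction: 0.08, soma_area_mean: 300.0, soma_area_sd: 110.0, nucleus_ratio: 0.45, markers: [Trpm8]}
  - {name: myelinated, fraction: 0.25, soma_area_mean: 700.0, soma_area_sd: 250.0, nucleus_ratio: 0.45, markers: [Thy1]}
  - {name: other,      fraction: 0.07, soma_area_mean: 450.0, soma_area_sd: 180.0, nucleus_ratio: 0.45, markers: []}
injury:
  axotomized_territories: [tibial, peroneal]
  survival_schedule:
    mrgprd:     {7: 1.0, 14: 0.100, 28: 0.060, 56: 0.050}
    cgrp:       {7: 1.0, 14: 0.3944444444, 28: 0.3377777778, 56: 0.3055555556}
    trpm8:      {7: 1.0, 14: 0.3944444444, 28: 0.3377777778, 56: 0.3055555556}
    myelinated: {7: 1.0, 14: 0.970, 28: 0.960, 56: 0.950}
    other:      {7: 1.0, 14: 0.3944444444, 28: 0.3377777778, 56: 0.3055555556}
labels:
  - {label: GFP,   target: axotomized, sensitivity: 0.991, false_positive: 0.046}
  - {label: tdTom, target: intact,     sensitivity: 1.0,   false_positive: 0.009}
  - {label: FB,    target: territory,  territory: tibial, sensitivity: 0.97, false_positive: 0.0}
sectioning: {thickness: 30.0, dz: 3.0, n_slides: 5, axial_shrinkage: 0.85, thickness_noise: 0.10}
timepoints: [7, 14, 28, 56]
readouts: [stereology]
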