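# Validation species: colony dimensions, chamber Reynolds numbers,
# skeletal porosities (oven-dry bulk vs aragonite true density), the
# dark-light illumination onsets, and the low/high-flow model warming
# values used to calibrate and check absorptivity at 600 W/m^2.
# absorptivity range measured for these corals: 0.13-0.28.
alpha_range: [0.13, 0.28]
species:
  - name: "Porites lobata"
    shape: hemisphere
    diameter_mm: 35
    scenario: steady
    Re_low: 72
    Re_high: 468
    porosity: 0.475
    porosity_assumed: false
    table6_model_low_K: 0.58
    table6_model_high_K: 0.52
    desk_resolution: [48, 26, 40]
  - name: "Stylophora pistillata"
    shape: cylinder
    diameter_mm: 6
    height_mm: 6
    scenario: steady
    Re_low: 12
    Re_high: 80
    porosity: 0.431
    porosity_assumed: false
    table6_model_low_K: 0.35
    table6_model_high_K: 0.21
    desk_resolution: [52, 28, 30]
  - name: "Favia sp."
    shape: hemisphere
    diameter_mm: 35
    scenario: steady
    Re_low: 72
    Re_high: 468
    porosity: 0.500
    porosity_assumed: true
    table6_model_low_K: 0.50
    table6_model_high_K: 0.35
    desk_resolution: [48, 26, 40]
  - name: "Cyphastrea serailia"
    shape: hemisphere
    diameter_mm: 50
    scenario: transient
    Re_low: 100
    Re_high: ~
    porosity: 0.500
    porosity_assumed: true
    t_on_s: 143
    desk_resolution: [48, 28, 44]
  - name: "Seriatopora hystrix"
    shape: cylinder
    diameter_mm: 3
    height_mm: 6
    scenario: transient
    Re_low: 6
    Re_high: ~
    porosity: 0.405
    porosity_assumed: false
    t_on_s: 235
    desk_resolution: [60, 38, 34]
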