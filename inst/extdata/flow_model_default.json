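{
  "note": "Approximate adult blood-volume partition for thoracic compartments, after ICRP Publication 89; values rounded and editable. Transit times are proportional to blood fraction, normalized to a 60 s full circulation. The out-of-field remainder receives no dose by default.",
  "compartments": [
    {"name": "lungs", "blood_fraction": 0.105, "transit_s": 6.3},
    {"name": "heart", "blood_fraction": 0.09, "transit_s": 5.4},
    {"name": "aorta", "blood_fraction": 0.04, "transit_s": 2.4},
    {"name": "pulmonary_artery", "blood_fraction": 0.035, "transit_s": 2.1},
    {"name": "vena_cava", "blood_fraction": 0.05, "transit_s": 3.0},
    {"name": "esophagus", "blood_fraction": 0.005, "transit_s": 0.3},
    {"name": "bronchi", "blood_fraction": 0.005, "transit_s": 0.3},
    {"name": "liver", "blood_fraction": 0.1, "transit_s": 6.0},
    {"name": "remainder", "blood_fraction": 0.57, "transit_s": 34.2}
  ]
}
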