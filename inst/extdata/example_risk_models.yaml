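# Example coefficient files for the three shipped covariate templates.
#
# The coefficients below are ILLUSTRATIVE, written in the style of the
# published lung-nodule calculator families (Mayo-style values transcribed
# from the clinical literature, the others approximate).  They are
# configuration, not part of the package: verify every value against the
# original publications before any applied use.
- name: gould_example
  template: gould
  intercept: -8.404
  coefficients:
    nodule_diameter_mm: 2.061
    age: 0.0779
    smoker_current: 0.7917
    years_quit: -0.567
- name: mayo_example
  template: mayo
  intercept: -6.8272
  coefficients:
    age: 0.0391
    smoker_current: 0.7917
    prior_cancer: 1.3388
    nodule_diameter_mm: 0.1274
    spiculation: 1.0407
    upper_lobe: 0.7838
- name: mcwilliams_example
  template: mcwilliams
  intercept: -6.6
  coefficients:
    age: 0.03
    sex: 0.6
    family_history: 0.3
    emphysema: 0.3
    nodule_diameter_mm: 1.8
    part_solid: 0.4
    upper_lobe: 0.6
    nodule_count: -0.05
    spiculation: 0.7
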