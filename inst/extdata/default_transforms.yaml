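transforms:
- name: hosp_n
  kind: capped_count
  cap: 6.0
- name: suic_att_n
  kind: capped_count
  cap: 6.0
- name: com_pd
  kind: binary
- name: bmi
  kind: categorical_bmi
  breaks:
  - 25.0
  - 30.0
  values:
  - 0.0
  - 0.5
  - 1.0
- name: mets
  kind: binary
- name: illness_n
  kind: capped_count
  cap: 4.0
- name: scip_cat
  kind: ordinal_map
  level_map:
    none: 0.0
    mild: 0.3333333
    moderate: 0.6666667
    severe: 1.0
- name: pd_x_bd
  kind: binary
- name: fast_total
  kind: linear_rescale
  lo: 0.0
  hi: 72.0
- name: fast_leisure
  kind: linear_rescale
  lo: 0.0
  hi: 6.0
- name: sf_pf
  kind: z_linear_clip
  z_best: 3.0
  z_worst: -3.0
- name: sf_mh
  kind: z_linear_clip
  z_best: 3.0
  z_worst: -3.0
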