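battery: EI-5
bands:
  pass_max: 1
  borderline_max: 3
missing_policy: error
components:
- name: CD
  direction: low_fails
  cuts: [6.0, 5.0, 4.0]
  valid_range: [1.0, 19.0]
  units: ACSS
  granularity: 1.0
- name: RCFT_Copy
  direction: low_fails
  cuts: [29.0, 25.0, 22.0]
  valid_range: [0.0, 36.0]
  units: raw
  granularity: 0.5
- name: FMS_WCST
  direction: high_fails
  cuts: [3.0, 4.0, 5.0]
  valid_range: [0.0, 30.0]
  units: raw
  granularity: 1.0
- name: RDS
  direction: low_fails
  cuts: [7.0, 6.0, 5.0]
  valid_range: [0.0, 20.0]
  units: raw
  granularity: 1.0
- name: RH_CVLT
  direction: low_fails
  cuts: [12.0, 11.0, 10.0]
  valid_range: [0.0, 16.0]
  units: raw
  granularity: 1.0
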