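reference: ''
region:
  start: 0
  length: 1000000
prototypes:
  K: 3
  n_snv: 100
  margin_fraction: 0.1
  substitution:
    p_het: 0.5
    tier_fractions:
    - 0.333333333333333
    - 0.333333333333333
    - 0.333333333333333
    matrix:
    - - 0.0
      - 0.21
      - 0.58
      - 0.21
    - - 0.21
      - 0.0
      - 0.21
      - 0.58
    - - 0.58
      - 0.21
      - 0.0
      - 0.21
    - - 0.21
      - 0.58
      - 0.21
      - 0.0
alpha:
- 0.1
- 0.3
- 0.6
units:
- id: unit1
  beta: 0.1
  samples:
  - id: unit1_s1_bulk
    type: bulk
    gamma: 0.1
    coverage: 24.0
    n_bulk_reads: 1000000
  - id: unit1_s2_sc
    type: single_cell
    gamma: 0.1
    coverage: 24.0
- id: unit2
  beta: 0.1
  samples:
  - id: unit2_s1_sc
    type: single_cell
    gamma: 0.1
    coverage: 24.0
  - id: unit2_s2_sc
    type: single_cell
    gamma: 0.1
    coverage: 24.0
- id: unit3
  beta: 0.1
  samples:
  - id: unit3_s1_bulk
    type: bulk
    gamma: 0.1
    coverage: 24.0
    n_bulk_reads: 1000000
  - id: unit3_s2_bulk
    type: bulk
    gamma: 0.1
    coverage: 24.0
    n_bulk_reads: 1000000
- id: unit4
  beta: 0.1
  samples:
  - id: unit4_s1_bulk
    type: bulk
    gamma: 0.1
    coverage: 24.0
    n_bulk_reads: 1000000
  - id: unit4_s2_sc
    type: single_cell
    gamma: 0.1
    coverage: 24.0
wga:
  ado_rate: 0.2
  fp_rate: 3.2e-05
reads:
  length: 100
  fragment_mean: 500.0
  fragment_sd: 50.0
  error_rate: 0.001
  base_quality: 30
seed: 1

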