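version: hcc-reference-1
markers:
- id: 1
  name: ALB
  divisions:
  - label: ALB > 3.5
    type: threshold
    op: '>'
    value: 3.5
  - label: ALB <= 3.5
    type: threshold
    op: <=
    value: 3.5
- id: 2
  name: tumor_burden
  divisions:
  - label: Tumor number x tumor size < 4
    type: threshold
    op: <
    value: 4.0
  - label: Tumor number x tumor size 4~9
    type: interval
    lower: 4.0
    upper: 9.0
    incl_lower: yes
    incl_upper: yes
  - label: Tumor number x tumor size > 9
    type: threshold
    op: '>'
    value: 9.0
- id: 3
  name: vp
  divisions:
  - label: vp+
    type: category
    values: +
  - label: vp-
    type: category
    values: '-'
- id: 4
  name: ICG
  divisions:
  - label: ICG < 15
    type: threshold
    op: <
    value: 15.0
  - label: ICG >= 15
    type: threshold
    op: '>='
    value: 15.0
- id: 5
  name: vv
  divisions:
  - label: vv+
    type: category
    values: +
  - label: vv-
    type: category
    values: '-'
- id: 6
  name: platelets
  divisions:
  - label: Number of platelets >= 10
    type: threshold
    op: '>='
    value: 10.0
  - label: Number of platelets < 10
    type: threshold
    op: <
    value: 10.0
- id: 7
  name: PT
  divisions:
  - label: PT >= 80
    type: threshold
    op: '>='
    value: 80.0
  - label: PT < 80
    type: threshold
    op: <
    value: 80.0
- id: 8
  name: bilirubin
  divisions:
  - label: Bilirubin < 1
    type: threshold
    op: <
    value: 1.0
  - label: Bilirubin >= 1
    type: threshold
    op: '>='
    value: 1.0
- id: 9
  name: differentiation
  divisions:
  - label: Degree of differentiation non-por
    type: category
    values: non-por
  - label: Degree of differentiation por
    type: category
    values: por
- id: 10
  name: liver_damage
  divisions:
  - label: Liver damage A
    type: category
    values: A
  - label: Liver damage B
    type: category
    values: B
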