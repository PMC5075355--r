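name: Tokyo Score
cutoff: 2
direction: '>='
markers:
  albumin:
  - label: albumin > 3.5
    points: 0
    type: threshold
    op: '>'
    value: 3.5
  - label: albumin 2.8~3.5
    points: 1
    type: interval
    lower: 2.8
    upper: 3.5
    incl_lower: yes
    incl_upper: yes
  - label: albumin < 2.8
    points: 2
    type: threshold
    op: <
    value: 2.8
  bilirubin:
  - label: bilirubin < 1
    points: 0
    type: threshold
    op: <
    value: 1.0
  - label: bilirubin 1~2
    points: 1
    type: interval
    lower: 1.0
    upper: 2.0
    incl_lower: yes
    incl_upper: yes
  - label: bilirubin > 2
    points: 2
    type: threshold
    op: '>'
    value: 2.0
  tumor_size:
  - label: tumor size < 2
    points: 0
    type: threshold
    op: <
    value: 2.0
  - label: tumor size 2~5
    points: 1
    type: interval
    lower: 2.0
    upper: 5.0
    incl_lower: yes
    incl_upper: yes
  - label: tumor size > 5
    points: 2
    type: threshold
    op: '>'
    value: 5.0
  tumor_number:
  - label: tumor number <= 3
    points: 0
    type: threshold
    op: <=
    value: 3.0
  - label: tumor number > 3
    points: 2
    type: threshold
    op: '>'
    value: 3.0
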