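- name: tis-A
  rt: 1.5
  response_factor: 1500.0
  adducts:
    '[M+H]+': 1.0
  inchikey: ZAAHLGHHOSNOOV-ZUVVCGBCCJ-N
  formula: C5H5N5
- name: tis-B
  rt: 4.5
  response_factor: 1500.0
  adducts:
    '[M+H]+': 1.0
  inchikey: ZAAHKGHHORNOOV-YUVVCFBCCJ-N
  formula: C4H9NO3
- name: tis-C
  rt: 7.5
  response_factor: 1500.0
  adducts:
    '[M+H]+': 1.0
  inchikey: ZAAHJGHHOQNOOV-XUVVCEBCCJ-N
  formula: C6H6N2O
- name: tis-D
  rt: 10.5
  response_factor: 1500.0
  adducts:
    '[M+H]+': 1.0
  inchikey: ZAAHIGHHOPNOOV-WUVVCDBCCJ-N
  formula: C3H7NO2S
- name: tis-E
  rt: 13.5
  response_factor: 1500.0
  adducts:
    '[M+H]+': 1.0
  inchikey: ZAAHHGHHOONOOV-VUVVCCBCCJ-N
  formula: C7H14N2O3
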