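- name: trigonelline-like
  rt: 7.46
  response_factor: 2000.0
  adducts:
    '[M+H]+': 0.8
    '[M+Na]+': 0.1
    '[M+K]+': 0.05
  inchikey: ZMSPZOEZODMFJU-IFBCPVSCRH-N
  formula: C7H7NO2
  fragments:
    '10':
    - rel_intensity: 100.0
      formula: C7H8NO2
    - rel_intensity: 35.0
      formula: C6H8N
    '30':
    - rel_intensity: 100.0
      formula: C6H8N
    - rel_intensity: 20.0
      formula: C6H6N
    - rel_intensity: 12.0
      formula: C5H4N
    - rel_intensity: 25.0
      formula: C7H8NO2
- name: aminobenzoate-like
  rt: 5.1
  response_factor: 1500.0
  adducts:
    '[M+H]+': 0.85
    '[M+Na]+': 0.05
  inchikey: IXDKUNDAVYUDHC-HAMTCRXEOH-N
  formula: C7H7NO2
  fragments:
    '10':
    - rel_intensity: 100.0
      formula: C7H8NO2
    - rel_intensity: 45.0
      formula: C7H6NO
    '30':
    - rel_intensity: 100.0
      formula: C7H6NO
    - rel_intensity: 30.0
      formula: C6H6N
    - rel_intensity: 40.0
      formula: C5H6N
- name: methylnicotinate-like
  rt: 6.7
  response_factor: 1200.0
  adducts:
    '[M+H]+': 0.9
    '[M+K]+': 0.05
  inchikey: QDSJJQJOORSRID-KVPCKPDJWL-N
  formula: C7H7NO2
  fragments:
    '10':
    - rel_intensity: 100.0
      formula: C7H8NO2
    - rel_intensity: 20.0
      formula: C6H8N
    '30':
    - rel_intensity: 100.0
      formula: C6H8N
    - rel_intensity: 35.0
      formula: C5H5
    - rel_intensity: 15.0
      formula: C3H4N
- name: glutamate-like
  rt: 11.0
  response_factor: 900.0
  adducts:
    '[M+H]+': 0.9
  inchikey: MRVSQBHKWBEDHW-QVZWUFLOAF-N
  formula: C5H9NO4
  fragments:
    '10':
    - rel_intensity: 100.0
      formula: C5H10NO4
    - rel_intensity: 55.0
      formula: C5H8NO3
    - rel_intensity: 20.0
      formula: C4H8NO2
    '30':
    - rel_intensity: 100.0
      formula: C4H8NO2
    - rel_intensity: 40.0
      formula: C4H6NO
    - rel_intensity: 30.0
      formula: C3H6N
- name: caffeine-like
  rt: 3.8
  response_factor: 1800.0
  adducts:
    '[M+H]+': 0.95
  inchikey: SREHBWPQENHWAF-ERUOJCDRAU-N
  formula: C8H10N4O2
  fragments:
    '10':
    - rel_intensity: 100.0
      formula: C8H11N4O2
    - rel_intensity: 18.0
      formula: C7H11N4O
    '30':
    - rel_intensity: 100.0
      formula: C6H8N3O
    - rel_intensity: 35.0
      formula: C5H8N3
    - rel_intensity: 40.0
      formula: C8H11N4O2
- name: decoy-early
  rt: 4.99
  response_factor: 2500.0
  adducts:
    '[M+H]+': 1.0
  inchikey: XKEFFUKHGPFCPJ-KKZPMLUKHU-N
  ion_mz: 138.0549549
  fragments:
    '10':
    - rel_intensity: 100.0
      mz: 53.25
    - rel_intensity: 60.0
      mz: 71.92
    '30':
    - rel_intensity: 100.0
      mz: 45.37
    - rel_intensity: 70.0
      mz: 58.81
    - rel_intensity: 30.0
      mz: 83.64
- name: decoy-late
  rt: 6.58
  response_factor: 2200.0
  adducts:
    '[M+H]+': 1.0
  inchikey: XKEFFUVSDALYST-TIJGROZMGH-N
  ion_mz: 138.0549549
  fragments:
    '10':
    - rel_intensity: 100.0
      mz: 61.44
    - rel_intensity: 40.0
      mz: 97.23
    '30':
    - rel_intensity: 100.0
      mz: 49.56
    - rel_intensity: 55.0
      mz: 76.18
    - rel_intensity: 25.0
      mz: 104.72
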