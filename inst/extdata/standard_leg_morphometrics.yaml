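L1:
  seg1_length_mm: 3.2
  seg1_mass_mg: 0.6
  seg2_length_mm: 2.8
  seg2_mass_mg: 0.9
L2:
  seg1_length_mm: 3.5
  seg1_mass_mg: 0.68
  seg2_length_mm: 3.0
  seg2_mass_mg: 1.02
L3:
  seg1_length_mm: 5.0
  seg1_mass_mg: 1.0
  seg2_length_mm: 4.0
  seg2_mass_mg: 1.5
R1:
  seg1_length_mm: 3.2
  seg1_mass_mg: 0.6
  seg2_length_mm: 2.8
  seg2_mass_mg: 0.9
R2:
  seg1_length_mm: 3.5
  seg1_mass_mg: 0.68
  seg2_length_mm: 3.0
  seg2_mass_mg: 1.02
R3:
  seg1_length_mm: 5.0
  seg1_mass_mg: 1.0
  seg2_length_mm: 4.0
  seg2_mass_mg: 1.5
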