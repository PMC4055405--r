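# Reciprocal F1 design: 16 plants per direction from crosses between an
# active (EG4-like) and an inactive (Nipponbare-like) strain.
design: reciprocal_f1
strain_a:
  name: EG4
  n_mping: 300
  loci_seed: 101
strain_b:
  name: Nipponbare
  n_mping: 50
  loci_seed: 102
n_per_direction: 16
detection_fraction: 0.1
target_per_plant: 15.5
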