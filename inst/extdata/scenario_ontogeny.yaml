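# Selfed ontogeny cohort: one parental plant (S0), eight selfed progenies
# (S1) sampled at endosperm, radicle and leaf blades 1-5, and twelve selfed
# progenies (S2) of the first S1 plant for inheritance scoring.
design: ontogeny_cohort
strain:
  name: EG4
  n_mping: 300
  loci_seed: 101
n_s1: 8
n_s2: 12
detection_fraction: 0.1
target_per_plant: 15.5
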