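# Landrace panel: 93 strains split into C-type Ping, T-type Ping and
# no-Ping groups with overdispersed mPing copy numbers (C-type shifted up).
design: ag_panel
n_c: 48
n_t: 14
n_none: 31
mu_base: 50
shift: 250
size_base: 8
size_c: 1.5
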