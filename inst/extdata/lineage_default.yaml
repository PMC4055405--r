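# Default rice ontogeny timeline (days after pollination).
# The SAM and radicle progenitor are regionalized in the proembryo at 3 DAP;
# leaf primordia 1-3 split from the SAM at 5, 6.5 and 8 DAP; leaves 4-5 are
# post-germination; the germline separates at the reproductive stage.
horizon: 20
compartments:
  - name: egg
    parents: []
    birth: -10
    gamete_origin: maternal
  - name: sperm_to_egg
    parents: []
    birth: -10
    gamete_origin: paternal
  - name: sperm_to_central
    parents: []
    birth: -10
    gamete_origin: paternal
  - name: polar_nuclei
    parents: []
    birth: -10
    gamete_origin: maternal
  - name: proembryo
    parents: [egg, sperm_to_egg]
    birth: 0
  - name: endosperm
    parents: [polar_nuclei, sperm_to_central]
    birth: 0
    tissue: E
  - name: SAM
    parents: [proembryo]
    birth: 3
  - name: radicle_progenitor
    parents: [proembryo]
    birth: 3
    tissue: R
  - name: L1
    parents: [SAM]
    birth: 5
    tissue: L1
  - name: L2
    parents: [SAM]
    birth: 6.5
    tissue: L2
  - name: L3
    parents: [SAM]
    birth: 8
    tissue: L3
  - name: L4
    parents: [SAM]
    birth: 12
    tissue: L4
  - name: L5
    parents: [SAM]
    birth: 15
    tissue: L5
  - name: germline
    parents: [SAM]
    birth: 60
    end: 70
    tissue: GERM
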