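# Worked example: chicken melanin study, project QMELA.
# Two phenotypes of chicken, skin extracts under two growth media,
# small-molecule test samples in two technical replicates.
project: QMELA
tiers:
  - tier: 1
    organism: chicken
    replicates: 1
    factors:
      - label: Phenotype
        levels: [black, yellow]
  - tier: 2
    tissue: Skin
    replicates: 1
    factors:
      - label: growth medium
        levels: [control, tyrosin-]
  - tier: 3
    analyte: Smallmolecules
    replicates: 2
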