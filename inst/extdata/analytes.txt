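# analyte (measurement substrate) vocabulary, one canonical token per line
DNA
RNA
Proteins
Peptides
Smallmolecules
Lipids
Metabolites
Cells
Carbohydrates
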