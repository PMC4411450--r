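# tissue vocabulary, one canonical token per line
Skin
Blood
Plasma
Serum
Liver
Brain
Heart
Kidney
Lung
Muscle
Bone
Bone marrow
Spleen
Pancreas
Intestine
Colon
Stomach
Tumor tissue
Cell culture
Whole organism
Leaf
Root
Stem
Seed
Feather
Egg
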