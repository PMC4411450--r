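Identifier	Sample type	Parent	Q_Primary_Tissue	Q_NCBI_Organism	Q_SAMPLE_TYPE	Q_EXTERNALDB_ID	XML_FACTORS
QMELAENTITY-1	Q_BIOLOGICAL_ENTITY			9031			Phenotype: black
QMELAENTITY-2	Q_BIOLOGICAL_ENTITY			9031			Phenotype: yellow
QMELA001AK	Q_BIOLOGICAL_SAMPLE	QMELAENTITY-1	Skin				Phenotype: black; growth medium: control
QMELA002B3	Q_BIOLOGICAL_SAMPLE	QMELAENTITY-1	Skin				Phenotype: black; growth medium: tyrosin-
QMELA003CK	Q_BIOLOGICAL_SAMPLE	QMELAENTITY-2	Skin				Phenotype: yellow; growth medium: control
QMELA004D3	Q_BIOLOGICAL_SAMPLE	QMELAENTITY-2	Skin				Phenotype: yellow; growth medium: tyrosin-
QMELA005AI	Q_TEST_SAMPLE	QMELA001AK			Smallmolecules		Phenotype: black; growth medium: control
QMELA006AQ	Q_TEST_SAMPLE	QMELA001AK			Smallmolecules		Phenotype: black; growth medium: control
QMELA007B9	Q_TEST_SAMPLE	QMELA002B3			Smallmolecules		Phenotype: black; growth medium: tyrosin-
QMELA008BH	Q_TEST_SAMPLE	QMELA002B3			Smallmolecules		Phenotype: black; growth medium: tyrosin-
QMELA009C0	Q_TEST_SAMPLE	QMELA003CK			Smallmolecules		Phenotype: yellow; growth medium: control
QMELA010C3	Q_TEST_SAMPLE	QMELA003CK			Smallmolecules		Phenotype: yellow; growth medium: control
QMELA011DK	Q_TEST_SAMPLE	QMELA004D3			Smallmolecules		Phenotype: yellow; growth medium: tyrosin-
QMELA012DS	Q_TEST_SAMPLE	QMELA004D3			Smallmolecules		Phenotype: yellow; growth medium: tyrosin-
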