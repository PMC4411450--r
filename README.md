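# qdesign

Factor-based experimental design and sample tracking for high-throughput
biology.

Multi-omics projects juggle hundreds of samples across organisms, tissue
extractions and measurement preparations, often handled by different labs.
Analyses, data sharing and reuse all depend on the metadata being right:
which organism, which treatment, which replicate, and which raw file came
from which sample. `qdesign` builds that bookkeeping *before* the data
exist. From a declarative specification it expands the complete sample
hierarchy, assigns checksummed identifiers, and writes the spreadsheets
and parameter files the rest of the pipeline consumes. It is aimed at
core-facility staff and bioinformaticians who set up experiments for wet
labs and need the design to be reproducible, validated and machine-usable.

## The model

An experiment is a tree over three tiers — biological entities (tier 1,
with an NCBI taxonomy id), sample extracts (tier 2, with a tissue) and
test samples prepared for measurement (tier 3, with an analyte). Each tier
varies zero or more factors and a replicate count; the engine creates all
permutations of the declared conditions multiplied by replicates,

n_k = n_(k−1) · ∏_f |levels(f)| · r_k,   n_0 = 1,

in a fixed, deterministic order. Superfluous samples of an asymmetric
design are deselected after each step and their descendants pruned.
Registration then assigns identifiers: entities get `<project>ENTITY-<n>`;
extracts and test samples get 10-character codes such as `QMELA005AI` —
project code (5), running counter (3 digits, shared by tiers 2–3), a group
letter (sequential per extract, inherited by its test samples) and a
weighted checksum character

C = map( Σᵢ ascii(sᵢ)·i mod 34 ),  alphabet `0`–`9`, `A`–`X`,

which catches transcription errors on tube labels and lets raw-file names
be scanned for embedded identifiers with essentially no false positives.

Factor metadata travels in a small XML schema (`<qfactors>`, validated
against the shipped `qfactors.xsd`, SI units enforced for continuous
values) and, inside the one-sample-per-row design TSV, as the condensed
`label: value; …` rendering. The TSV can be edited by collaborators and
merged back; sample sheets for the labs and MaxQuant experimental-design
files (`Name`/`Fraction`/`Experiment`) are generated from the same state.

## Worked example

The bundled spec describes a chicken melanin study: two phenotypes, skin
extracts under two growth media, small-molecule test samples in two
technical replicates.

```r
library(qdesign)

spec <- read_design_spec(system.file("extdata", "qmela_spec.yaml",
                                     package = "qdesign"))
design <- register_design(build_design(spec))
design
#> Design for project QMELA (registered)
#>   tiers: 2 entities / 4 extracts / 8 test samples

cat(write_design_tsv(design))
#> Identifier	Sample type	Parent	Q_Primary_Tissue	Q_NCBI_Organism	Q_SAMPLE_TYPE	Q_EXTERNALDB_ID	XML_FACTORS
#> QMELAENTITY-1	Q_BIOLOGICAL_ENTITY			9031			Phenotype: black
#> QMELAENTITY-2	Q_BIOLOGICAL_ENTITY			9031			Phenotype: yellow
#> QMELA001AK	Q_BIOLOGICAL_SAMPLE	QMELAENTITY-1	Skin				Phenotype: black; growth medium: control
#> ...
#> QMELA012DS	Q_TEST_SAMPLE	QMELA004D3			Smallmolecules		Phenotype: yellow; growth medium: tyrosin-
```

Two entities (the phenotypes), four extracts (phenotype × growth medium,
counters 001–004, group letters A–D), eight test samples (two technical
replicates per extract, counters 005–012, inheriting their parent's
letter). Each row carries its full treatment history in `XML_FACTORS`.

Identifier utilities:

```r
validate_id("QMELA011DL")$reason
#> "bad-checksum"
scan_filename("QMELA005AI_run1.raw")
#> "QMELA005AI"
```

MaxQuant export, grouped by growth medium:

```r
s3 <- design_samples(design, 3)
ids <- vapply(s3, `[[`, "", "identifier")
mq <- maxquant_design(s3, setNames(paste0(ids, ".raw"), ids),
                      group_by = "growth medium")
cat(write_maxquant(mq))
#> Name	Fraction	Experiment
#> QMELA005AI	1	control
#> QMELA006AQ	1	control
#> QMELA007B9	1	tyrosin-
#> ...
```

The same flows are available from the shell through the `exec/qdesign`
script (`new`, `derive`, `check`, `sheet`, `maxquant`, `checksum`,
`validate-id`, `scan`, `factors`, ...), e.g.

```sh
Rscript exec/qdesign new --spec qmela_spec.yaml -o design.tsv
Rscript exec/qdesign maxquant design.tsv --files files.tsv \
        --group-by "growth medium" -o experimentalDesign.txt
```

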