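---
title: "Factor-based experimental design: model, identifiers and exchange formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-based experimental design: model, identifiers and exchange formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdesign)
```

## The problem

High-throughput biological experiments routinely involve hundreds of
samples handled across several labs and measurement facilities. Most of
what can be done with the resulting data — statistical analysis, failure
diagnosis, reuse, sharing — depends on accurate metadata: which organism,
which tissue, which treatment, which replicate, and how each measured file
relates to the material it came from. qdesign generates that bookkeeping
up front, before any data exist: it expands a declarative description of
the experiment into a complete sample hierarchy, assigns error-detecting
identifiers, and emits the spreadsheets and parameter files the downstream
steps consume.

## The three-tier model

A design is a tree over three tiers:

1. **Biological entities** — the organisms or systems under study
   (patients, animals, plants, cell lines). Fixed property: the NCBI
   taxonomy id of the species.
2. **Sample extracts** — tissue or cells taken from an entity. Fixed
   property: the tissue.
3. **Test samples** — material prepared for a measurement technology
   (DNA for sequencing, peptides or small molecules for MS). Fixed
   property: the analyte.

Each tier can vary any number of experimental **factors** (phenotype,
growth medium, dose, ...), each with two or more levels, and carries a
replicate count — biological replicates at tiers 1–2, technical replicates
at tier 3. The expansion engine treats the two identically (a replicate is
a multiplicity); the distinction is purely descriptive.

## Factorial expansion

`expand_tier()` builds each tier as the cartesian product

\[ n_k \;=\; n_{k-1} \cdot \prod_{f \in F_k} |{\rm levels}(f)| \cdot r_k,
   \qquad n_0 = 1, \]

where \(F_k\) are the factors declared at tier \(k\) and \(r_k\) its
replicate count. The ordering is fixed: parents outermost, then factor
combinations with the first declared factor varying slowest, then
replicates innermost. Fixing the order makes every run byte-reproducible,
which is what allows exact golden tests on the exported files and means
two people running the same spec always obtain the same sheet. Each sample
accumulates its ancestors' factor values plus its own, so a tier-3 row is
self-describing without walking the tree.

The product is fully symmetric by construction. Real designs often are
not, so samples can be **deselected** after each expansion step
(`deselect()`); removal cascades to all descendants and preserves the
order of the survivors. Identifiers are assigned only afterwards, at
registration, so exported tables never contain counter gaps.

```{r}
spec <- read_design_spec(system.file("extdata", "qmela_spec.yaml",
                                     package = "qdesign"))
design <- register_design(build_design(spec))
design
```

## Identifiers and the weighted checksum

Registration (`register_design()`) assigns each sample a project-scoped
identifier designed to be printed on labels, scanned from barcodes and
embedded in raw-data file names:

* entities: `<project>ENTITY-<n>`, unpadded, no checksum;
* extracts and test samples: a fixed-width 10-character code
  `PPPPP` `ddd` `G` `C` — the 5-character project code (`Q` plus four
  uppercase alphanumerics), a 3-digit zero-padded counter shared by tiers
  2 and 3, a group letter, and a checksum character.

The group letter is assigned sequentially to extracts (`A`, `B`, `C`, ...,
wrapping after `Z`) and inherited by their test samples, so all material
derived from one extract shares the 9th character — convenient when
sorting tubes by hand. The checksum is

\[ C = {\rm map}\Big( \sum_{i} {\rm ascii}(s_i)\, i \;\bmod\; 34 \Big), \]

over the first nine characters \(s_1\ldots s_9\) with 1-based position
weights, mapped onto the 34-character alphabet `0`–`9`, `A`–`X`. Position
weighting makes the check sensitive to transpositions as well as
substitutions; any edit of the checksum character itself is always caught
(tested exhaustively), and a single substitution elsewhere escapes only if
its weighted contribution happens to be divisible by 34.
`scan_filename()` exploits the checksum in the other direction: it slides
a 10-character window over a file name and keeps the substrings that
re-checksum, so no delimiter convention is imposed on file naming.

Counters are fixed-width. A project can hold at most 999 registered
extract/test samples; exceeding that is a hard error suggesting a new
project code, because silently widening the counter would shift the
checksum positions of every later identifier.

## Factor metadata: XML and condensed forms

Factor values travel in two serializations:

* the **XML form** — a `<qfactors>` document with `<qcategorical
  label value>` and `<qcontinuous label value unit>` children, validated
  against the `qfactors.xsd` schema shipped with the package. Continuous
  values must carry a unit from the shipped SI table (the seven base units
  plus prefixed gram/litre/mole/molar/metre/second forms; matching is
  case-sensitive, and non-SI units such as °C are rejected). This form is
  authoritative.
* the **condensed form** — the human-readable `label: value; label: value
  unit` string placed in the TSV's `XML_FACTORS` column. Parsing treats a
  value as continuous exactly when it has the shape `<number> <token>`
  with the token in the unit table; everything else stays categorical, so
  level names with trailing hyphens (`tyrosin-`) are safe. The condensed
  form is presentational: a categorical value that coincidentally looks
  like `5 mg` would be re-read as continuous. We accept this ambiguity and
  document it rather than escaping, because the column must stay pleasant
  to read and edit in a spreadsheet.

Element and attribute names of the XML schema are this package's
convention, published as an XSD so third parties can validate documents
independently.

## The TSV exchange format

The design table is one sample per row with eight canonical columns
(`Identifier`, `Sample type`, `Parent`, `Q_Primary_Tissue`,
`Q_NCBI_Organism`, `Q_SAMPLE_TYPE`, `Q_EXTERNALDB_ID`, `XML_FACTORS`),
custom property columns appended after `XML_FACTORS`. Dialect choices:
UTF-8, Unix newlines, no quoting — tabs and newlines are forbidden inside
cells instead of escaped, because escaping dialects are where spreadsheet
round trips break. Empty string denotes an absent value. Rows are written
tier 1, 2, 3, within tier by counter.

`read_design_tsv()` re-validates everything on the way back in: checksums,
parent references (each parent must appear earlier in the table and be of
the adjacent tier), duplicate identifiers, and the factor grammar, each
error naming its row. `merge_edits()` implements the fill-in/reupload
cycle: `Identifier`, `Sample type` and `Parent` are immutable, non-empty
cells of the canonical property columns overwrite stored values, the
`XML_FACTORS` cell is authoritative (an empty cell clears the values), and
any unknown column becomes a custom property on the rows where its cell is
non-empty. The merge is idempotent, so an accidental double upload is
harmless.

## Derived designs

Follow-up experiments attach new tiers beneath samples that are already
registered (`derive_from_existing()`): the parents keep their identifiers,
the new samples inherit their factor values, and the counter continues
after the largest counter among all known samples of the project. Where to
restart the group letter is not observable from a single export, so the
same continuation rule is applied: new extracts continue after the largest
group letter seen, wrapping after `Z` (the letter is non-unique by
construction, so wrapping cannot collide). Post-registration deselection
is deliberately unsupported — renumbering registered identifiers would
orphan any label already printed.

## The random-spec generator

Property tests and the acceptance script draw random specifications with
`random_design_spec()`: up to 3 factors per tier with up to 4 levels each
(a quarter of them continuous, with random SI units), up to 3 replicates,
and organism/tissue/analyte drawn from the bundled vocabularies — the
scale of a typical facility project. Expansions are capped at 200 tier-3
samples; larger draws are rejected and redrawn. The generator emulates the
*structure* of real designs, not their content: labels and levels are
random tokens, factors are independent across tiers, and every design is
a tree (no pooling). Passing round-trip and count-law suites on these
fixtures therefore demonstrates the bookkeeping machinery, not anything
about real biology; the worked chicken-melanin example is what ties the
output format to a concrete experiment. Deterministic sizes used by the
checks: 200 random specs for the count law, 100 designs for TSV round
trips, 200 value lists for the serialization round trips, 10,000 random
stems for the checksum oracle comparison.

## Numerical and degenerate-input choices

* Continuous factor values are rendered without scientific notation at up
  to 15 significant digits, which round-trips every value the generator or
  a lab spreadsheet realistically produces.
* An empty factor list serializes to `<qfactors/>` and to the empty
  string; both parse back to an empty list.
* A design in which every tier-1 sample was deselected is valid (all tiers
  empty) and exports as a header-only table.
* Vocabulary matching is case-insensitive for organism names, tissues and
  analytes (lab spreadsheets are case-inconsistent) and exact for
  taxonomy ids and SI units, where case carries meaning.
* Unknown organisms, tissues and analytes fail with the closest known
  entries (edit distance) to catch typos at spec-validation time, before
  any expansion.

## Limitations

* The tier count is fixed at three. The underlying model generalizes, but
  the identifier grammar and the TSV layout are specific to the
  entity/extract/test-sample hierarchy, so extension is out of scope here.
* Generated designs are trees: pooling (a sample with several parents) is
  representable in the data model and the TSV, but never produced by the
  expansion.
* The bundled vocabularies are small, editable reconstructions — enough
  for offline validation, not a taxonomy or ontology service.
* No statistical design support: no power analysis, blocking or
  randomization; the engine enumerates and tracks samples, it does not
  choose them.
* MaxQuant export targets the classic three-column
  `experimentalDesignTemplate` (`Name`, `Fraction`, `Experiment`); how
  experiment labels are derived (by a chosen factor, or one group per
  project) is this package's convention.
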