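# Shared fixtures: the chicken-melanin worked example (project QMELA) built
# in code, its expected export, and an independent brute-force checksum
# oracle kept deliberately separate from the package's implementation.

# literal sum-of-code-times-position loop; the alphabet is spelled out
oracle_checksum <- function(stem) {
  chars <- strsplit(stem, "")[[1L]]
  total <- 0
  for (i in seq_along(chars)) {
    total <- total + as.integer(charToRaw(chars[i])) * i
  }
  alphabet <- c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                "A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
                "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W", "X")
  alphabet[(total %% 34) + 1L]
}

random_ascii_stem <- function(max_len = 12L) {
  pool <- c(LETTERS, letters, 0:9, "_", "-", ".")
  paste(sample(pool, sample.int(max_len, 1L), replace = TRUE), collapse = "")
}

# the worked example: two chicken phenotypes, skin extracts under two growth
# media, small-molecule test samples in two technical replicates
qmela_spec <- function() {
  design_spec("QMELA", list(
    tier_spec(1, factors = list(factor_def("Phenotype", c("black", "yellow"))),
              replicates = 1, organism = "chicken"),
    tier_spec(2, factors = list(factor_def("growth medium",
                                           c("control", "tyrosin-"))),
              replicates = 1, tissue = "Skin"),
    tier_spec(3, replicates = 2, analyte = "Smallmolecules")
  ))
}

qmela_design <- function() register_design(build_design(qmela_spec()))

golden_tsv_path <- function() {
  system.file("extdata", "qmela_design.tsv", package = "qdesign")
}

golden_tsv <- function() {
  paste0(paste(readLines(golden_tsv_path(), encoding = "UTF-8", warn = FALSE),
               collapse = "\n"), "\n")
}

GOLDEN_SAMPLE_IDS <- c("QMELA001AK", "QMELA002B3", "QMELA003CK", "QMELA004D3",
                       "QMELA005AI", "QMELA006AQ", "QMELA007B9", "QMELA008BH",
                       "QMELA009C0", "QMELA010C3", "QMELA011DK", "QMELA012DS")
GOLDEN_ENTITY_IDS <- c("QMELAENTITY-1", "QMELAENTITY-2")

# comparable projection of a design's observable state
design_signature <- function(design) {
  lapply(design_samples(design), function(s) {
    props <- s$properties[lengths(s$properties) > 0 &
                            nzchar(as.character(s$properties))]
    list(id = s$identifier, type = s$type, parents = s$parents,
         factors = to_condensed(s$factor_values),
         props = props[order(names(props))])
  })
}

condensed_list <- function(values) to_condensed(values)
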