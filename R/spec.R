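# Declarative description of a 3-tier experiment: project code plus one
# TierSpec per tier (factors, replicate count, fixed properties). Validation
# resolves every vocabulary reference up front, so a spec that constructs
# cleanly expands without further vocabulary errors.

QD_SAMPLE_TYPES <- c("Q_BIOLOGICAL_ENTITY", "Q_BIOLOGICAL_SAMPLE", "Q_TEST_SAMPLE")
QD_CANONICAL_COLUMNS <- c("Identifier", "Sample type", "Parent",
                          "Q_Primary_Tissue", "Q_NCBI_Organism",
                          "Q_SAMPLE_TYPE", "Q_EXTERNALDB_ID", "XML_FACTORS")
QD_CANONICAL_PROPS <- c("Q_Primary_Tissue", "Q_NCBI_Organism",
                        "Q_SAMPLE_TYPE", "Q_EXTERNALDB_ID")

#' Describe one tier of an experiment
#'
#' Tiers: 1 = biological entities (patients, animals, plants; requires an
#' organism), 2 = sample extracts (tissues or cells; requires a tissue),
#' 3 = test samples prepared for measurement (requires an analyte such as
#' `"Proteins"` or `"Smallmolecules"`). Replicates multiply the tier:
#' biological replicates at tiers 1-2, technical replicates at tier 3 — the
#' expansion treats them identically.
#'
#' @param tier 1, 2 or 3.
#' @param factors List of [factor_def()] objects varied at this tier.
#' @param replicates Positive integer.
#' @param organism Organism name, alias or taxonomy id (tier 1).
#' @param tissue Tissue token (tier 2).
#' @param analyte Analyte token (tier 3).
#' @param properties Named list of additional fixed properties copied onto
#'   every sample of the tier.
#' @return Object of class `qd_tier_spec`.
#' @export
tier_spec <- function(tier, factors = list(), replicates = 1L,
                      organism = NULL, tissue = NULL, analyte = NULL,
                      properties = list()) {
  tier <- as.integer(tier)
  if (is.na(tier) || !tier %in% 1:3)
    stop("tier must be 1, 2 or 3", call. = FALSE)
  if (inherits(factors, "qd_factor")) factors <- list(factors)
  if (!all(vapply(factors, inherits, TRUE, "qd_factor")))
    stop("factors must be a list of factor_def() objects", call. = FALSE)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be a positive integer", call. = FALSE)
  structure(list(tier = tier, factors = factors, replicates = replicates,
                 organism = organism, tissue = tissue, analyte = analyte,
                 properties = properties),
            class = "qd_tier_spec")
}

#' Assemble and validate a full design specification
#'
#' Checks the project-code grammar, requires exactly three tiers in order,
#' and resolves every vocabulary reference: the tier-1 organism to an NCBI
#' taxonomy id, the tier-2 tissue and tier-3 analyte to their canonical
#' tokens. Vocabulary failures surface here, before any expansion.
#'
#' @param project 5-character project code ('Q' + 4 uppercase
#'   alphanumerics), e.g. `"QMELA"`.
#' @param tiers List of exactly three [tier_spec()] objects, tiers 1, 2, 3.
#' @param vocab A `qd_vocabulary`.
#' @return Object of class `qd_design_spec` with resolved fixed properties.
#' @export
design_spec <- function(project, tiers, vocab = load_vocabulary()) {
  assert_project_code(project)
  if (length(tiers) != 3L || !all(vapply(tiers, inherits, TRUE, "qd_tier_spec")))
    stop("a design needs exactly 3 tier_spec() objects", call. = FALSE)
  if (!identical(vapply(tiers, `[[`, 0L, "tier"), 1:3))
    stop("tiers must be supplied in order 1, 2, 3", call. = FALSE)

  t1 <- tiers[[1L]]; t2 <- tiers[[2L]]; t3 <- tiers[[3L]]
  if (is.null(t1$organism))
    stop("tier 1 needs an organism", call. = FALSE)
  t1$properties$Q_NCBI_Organism <- as.character(resolve_taxon(t1$organism, vocab))
  if (is.null(t2$tissue))
    stop("tier 2 needs a tissue", call. = FALSE)
  v <- validate_vocab_token("tissues", t2$tissue, vocab)
  if (!v$accepted)
    stop("unknown tissue '", t2$tissue, "'; closest known: ",
         paste(v$suggestions, collapse = ", "), call. = FALSE)
  t2$properties$Q_Primary_Tissue <- v$token
  if (is.null(t3$analyte))
    stop("tier 3 needs an analyte", call. = FALSE)
  v <- validate_vocab_token("analytes", t3$analyte, vocab)
  if (!v$accepted)
    stop("unknown analyte '", t3$analyte, "'; closest known: ",
         paste(v$suggestions, collapse = ", "), call. = FALSE)
  t3$properties$Q_SAMPLE_TYPE <- v$token

  structure(list(project = project, tiers = list(t1, t2, t3)),
            class = "qd_design_spec")
}

#' @export
print.qd_design_spec <- function(x, ...) {
  cat("Design spec for project", x$project, "\n")
  for (t in x$tiers) {
    facs <- if (length(t$factors) == 0L) "no factors"
            else paste(vapply(t$factors, function(f)
              paste0(f$label, "{", paste(f$levels, collapse = ", "), "}"),
              ""), collapse = " x ")
    cat("  tier ", t$tier, ": ", facs, ", replicates ", t$replicates, "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a design specification from a YAML file
#'
#' The file holds the project code and one block per tier with its factors
#' (label plus levels, and a unit for numeric levels), replicate count and
#' organism/tissue/analyte. See `system.file("extdata", "qmela_spec.yaml",
#' package = "qdesign")` for a complete example.
#'
#' @param path YAML file path.
#' @param vocab A `qd_vocabulary`.
#' @return A validated `qd_design_spec`.
#' @export
read_design_spec <- function(path, vocab = load_vocabulary()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$project) || is.null(raw$tiers))
    stop("spec file needs 'project' and 'tiers' keys", call. = FALSE)
  tiers <- lapply(raw$tiers, function(t) {
    factors <- lapply(t$factors, function(f) {
      if (is.null(f$label) || is.null(f$levels))
        stop("each factor needs 'label' and 'levels'", call. = FALSE)
      levels <- unlist(f$levels, use.names = FALSE)
      factor_def(f$label, levels, unit = f$unit)
    })
    tier_spec(tier = t$tier, factors = factors,
              replicates = t$replicates %||% 1L,
              organism = t$organism, tissue = t$tissue, analyte = t$analyte,
              properties = t$properties %||% list())
  })
  design_spec(raw$project, tiers, vocab)
}
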