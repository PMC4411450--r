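# Random design specifications for property testing. Draws factor counts,
# level counts, replicate numbers and vocabulary picks from the ranges a
# real multi-omics facility sees (up to 3 factors of up to 4 levels per
# tier, up to 3 replicates), rejecting combinations that would exceed a
# size cap. Uses R's RNG: set a seed for reproducibility.

random_label <- function(n_chars = 6L) {
  paste(sample(letters, n_chars, replace = TRUE), collapse = "")
}

random_factor <- function(label, max_levels = 4L, p_continuous = 0.25) {
  n <- sample.int(max_levels - 1L, 1L) + 1L # 2..max_levels levels
  if (stats::runif(1) < p_continuous) {
    levels <- sort(sample.int(500L, n)) / 10
    factor_def(label, levels, unit = sample(si_units(), 1L))
  } else {
    factor_def(label, paste0("lv", sample.int(99L, n)))
  }
}

#' Draw a random design specification
#'
#' Generates a valid 3-tier specification with random factors (categorical
#' and continuous), levels, replicate counts and vocabulary selections, for
#' property tests of the expansion, registration and serialization
#' machinery. Factor labels are unique across tiers. Specs whose full
#' expansion would exceed `max_samples` tier-3 samples are redrawn.
#'
#' @param vocab A `qd_vocabulary`.
#' @param max_factors,max_levels,max_replicates Per-tier upper bounds.
#' @param max_samples Cap on the tier-3 size of the expanded design.
#' @return A `qd_design_spec`.
#' @export
random_design_spec <- function(vocab = load_vocabulary(), max_factors = 3L,
                               max_levels = 4L, max_replicates = 3L,
                               max_samples = 200L) {
  repeat {
    labels <- unique(replicate(12L, random_label()))
    li <- 0L
    tiers <- lapply(1:3, function(k) {
      n_fac <- sample.int(max_factors + 1L, 1L) - 1L # 0..max_factors
      factors <- lapply(seq_len(n_fac), function(j) {
        li <<- li + 1L
        random_factor(labels[li], max_levels)
      })
      tier_spec(k, factors = factors,
                replicates = sample.int(max_replicates, 1L),
                organism = if (k == 1L) sample(names(vocab$taxa), 1L),
                tissue = if (k == 2L) sample(vocab$tissues, 1L),
                analyte = if (k == 3L) sample(vocab$analytes, 1L))
    })
    size <- 1
    for (ts in tiers) {
      size <- size * ts$replicates *
        prod(vapply(ts$factors, function(f) length(f$levels), 0))
    }
    if (size <= max_samples) {
      project <- paste0("Q", paste(sample(LETTERS, 4L, replace = TRUE),
                                   collapse = ""))
      return(design_spec(project, tiers, vocab))
    }
  }
}

#' Draw a random list of factor values
#'
#' Standalone value lists (unique labels, mixed categorical/continuous) for
#' round-trip tests of the XML and condensed serializations.
#'
#' @param max_values Maximum number of label/value pairs.
#' @return List of `qd_factor_value` (possibly empty).
#' @export
random_factor_values <- function(max_values = 5L) {
  n <- sample.int(max_values + 1L, 1L) - 1L
  labels <- character(0)
  while (length(labels) < n) labels <- unique(c(labels, random_label()))
  lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.3)
      factor_value(labels[i], sample.int(1000L, 1L) / 4,
                   sample(si_units(), 1L))
    else
      factor_value(labels[i], paste0("val ", sample.int(999L, 1L)))
  })
}
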