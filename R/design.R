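# The factorial expansion engine. A design is built tier by tier: each tier
# is the cartesian product of its parents, its factor levels and its
# replicate count, every sample inheriting its ancestors' factor values.
# Superfluous samples of an asymmetric design are deselected before
# registration; identifiers are assigned only at registration, so printed
# designs never contain counter gaps. The whole pipeline is deterministic.

new_sample <- function(type, parent_index = NA_integer_, factor_values = list(),
                       properties = list(), identifier = "",
                       parents = character(0)) {
  structure(list(identifier = identifier, type = type,
                 parent_index = parent_index, parents = parents,
                 factor_values = factor_values, properties = properties),
            class = "qd_sample")
}

#' @export
format.qd_sample <- function(x, ...) {
  id <- if (nzchar(x$identifier)) x$identifier else "<unregistered>"
  paste0(id, " [", x$type, "] ", to_condensed(x$factor_values))
}

#' @export
print.qd_sample <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

sample_tier <- function(sample) match(sample$type, QD_SAMPLE_TYPES)

# all factor-level combinations, first declared factor varying slowest
factor_combos <- function(factors) {
  combos <- list(list())
  for (f in factors) {
    grown <- vector("list", length(combos) * length(f$levels))
    k <- 0L
    for (combo in combos) {
      for (lv in f$levels) {
        fv <- if (f$kind == "continuous") factor_value(f$label, lv, f$unit)
              else factor_value(f$label, lv)
        k <- k + 1L
        grown[[k]] <- c(combo, list(fv))
      }
    }
    combos <- grown
  }
  combos
}

#' Expand one tier of a design
#'
#' Produces `length(parents) * prod(levels per factor) * replicates` samples
#' (one virtual parent for tier 1). Ordering is deterministic: parents
#' outermost, then factor-level combinations in declared order (first factor
#' slowest), replicates innermost. Each sample accumulates its parent's
#' factor values plus this tier's combination and records its single parent.
#'
#' @param parents List of `qd_sample` from the previous tier, or `NULL` for
#'   tier 1.
#' @param factors List of [factor_def()] objects (may be empty).
#' @param replicates Positive integer.
#' @param type Sample type token of the new tier.
#' @param properties Named list of fixed properties stamped onto every new
#'   sample.
#' @return List of unregistered `qd_sample`.
#' @export
expand_tier <- function(parents, factors, replicates,
                        type = "Q_BIOLOGICAL_ENTITY", properties = list()) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be >= 1", call. = FALSE)
  if (!all(vapply(factors, inherits, TRUE, "qd_factor")))
    stop("factors must be factor_def() objects", call. = FALSE)
  if (any(vapply(factors, function(f) length(f$levels), 0L) == 0L))
    stop("every factor needs at least one level", call. = FALSE)
  combos <- factor_combos(factors)
  root <- is.null(parents)
  n_par <- if (root) 1L else length(parents)
  out <- vector("list", n_par * length(combos) * replicates)
  k <- 0L
  for (pi in seq_len(n_par)) {
    inherited <- if (root) list() else parents[[pi]]$factor_values
    for (combo in combos) {
      for (r in seq_len(replicates)) {
        k <- k + 1L
        out[[k]] <- new_sample(type,
                               parent_index = if (root) NA_integer_ else pi,
                               factor_values = c(inherited, combo),
                               properties = properties)
      }
    }
  }
  out
}

#' Build the full 3-tier hierarchy from a design specification
#'
#' Applies [expand_tier()] for tiers 1 to 3, so tier sizes obey
#' `n_k = n_(k-1) * prod(levels) * replicates_k` (with `n_0 = 1`). Fixed
#' properties of each tier (taxonomy id, tissue, analyte, extras) are copied
#' onto every sample of that tier. The result is unregistered: identifiers
#' are assigned by [register_design()] after any [deselect()] calls.
#'
#' @param spec A validated `qd_design_spec`.
#' @return Object of class `qd_design`.
#' @examples
#' spec <- read_design_spec(system.file("extdata", "qmela_spec.yaml",
#'                                      package = "qdesign"))
#' design <- build_design(spec)
#' tier_sizes(design) # 2 4 8
#' @export
build_design <- function(spec) {
  if (!inherits(spec, "qd_design_spec"))
    stop("build_design() needs a qd_design_spec", call. = FALSE)
  tiers <- vector("list", 3L)
  parents <- NULL
  for (k in 1:3) {
    ts <- spec$tiers[[k]]
    tiers[[k]] <- expand_tier(parents, ts$factors, ts$replicates,
                              type = QD_SAMPLE_TYPES[k],
                              properties = ts$properties)
    parents <- tiers[[k]]
  }
  new_design(spec$project, tiers)
}

new_design <- function(project, tiers, registered = FALSE,
                       counter_start = 0L, entity_start = 0L,
                       group_start = 0L) {
  structure(list(project = project, tiers = tiers, registered = registered,
                 counter_start = counter_start, entity_start = entity_start,
                 group_start = group_start),
            class = "qd_design")
}

#' Tier sizes of a design
#' @param design A `qd_design`.
#' @return Integer vector of length 3.
#' @export
tier_sizes <- function(design) {
  vapply(design$tiers, length, 0L)
}

#' @export
print.qd_design <- function(x, ...) {
  sizes <- tier_sizes(x)
  cat("Design for project ", x$project, " (",
      if (x$registered) "registered" else "unregistered", ")\n", sep = "")
  cat("  tiers: ", sizes[1], " entities / ", sizes[2], " extracts / ",
      sizes[3], " test samples\n", sep = "")
  invisible(x)
}

#' Remove samples from an unregistered design
#'
#' Deselection represents asymmetric designs: the factorial expansion is
#' fully symmetric, and samples not part of the actual experiment are
#' removed afterwards, together with all their descendants in later tiers.
#' Remaining order is preserved. Registered designs cannot be edited — they
#' would acquire counter gaps — so deselection must happen before
#' [register_design()].
#'
#' @param design Unregistered `qd_design`.
#' @param tier 1, 2 or 3.
#' @param positions Integer positions within the tier to remove.
#' @return The pruned `qd_design`.
#' @export
deselect <- function(design, tier, positions) {
  if (!inherits(design, "qd_design"))
    stop("deselect() needs a qd_design", call. = FALSE)
  if (design$registered)
    stop("cannot deselect from a registered design", call. = FALSE)
  tier <- as.integer(tier)
  if (is.na(tier) || !tier %in% 1:3)
    stop("tier must be 1, 2 or 3", call. = FALSE)
  positions <- unique(as.integer(positions))
  if (length(positions) == 0L) return(design)
  n <- length(design$tiers[[tier]])
  if (anyNA(positions) || any(positions < 1L | positions > n))
    stop("deselect positions out of range 1-", n, " for tier ", tier,
         call. = FALSE)
  drop <- positions
  for (k in tier:3) {
    keep <- setdiff(seq_along(design$tiers[[k]]), drop)
    # old position -> new position of survivors, for parent reindexing
    remap <- rep(NA_integer_, length(design$tiers[[k]]))
    remap[keep] <- seq_along(keep)
    design$tiers[[k]] <- design$tiers[[k]][keep]
    if (k == 3L) break
    child_parents <- vapply(design$tiers[[k + 1L]],
                            `[[`, NA_integer_, "parent_index")
    drop <- which(child_parents %in% positions)
    design$tiers[[k + 1L]] <- lapply(design$tiers[[k + 1L]], function(s) {
      if (!is.na(s$parent_index)) s$parent_index <- remap[s$parent_index]
      s
    })
    positions <- drop
    if (length(drop) == 0L) {
      # nothing cascades further; deeper tiers keep their indices
      break
    }
  }
  design
}

max_sample_counter <- function(ids) {
  counters <- vapply(ids, function(id) {
    v <- validate_id(id)
    if (v$valid && v$form == "sample") parse_id(id)$counter else 0L
  }, 0L)
  if (length(counters) == 0L) 0L else max(counters)
}

max_entity_index <- function(ids) {
  idx <- vapply(ids, function(id) {
    v <- validate_id(id)
    if (v$valid && v$form == "entity") parse_id(id)$entity_index else 0L
  }, 0L)
  if (length(idx) == 0L) 0L else max(idx)
}

max_group_index <- function(ids) {
  idx <- vapply(ids, function(id) {
    v <- validate_id(id)
    if (v$valid && v$form == "sample")
      match(parse_id(id)$group_char, LETTERS) else 0L
  }, 0L)
  if (length(idx) == 0L) 0L else max(idx)
}

#' Assign identifiers to a design
#'
#' Registration freezes the design and assigns identifiers: tier-1 samples
#' get `<project>ENTITY-<n>` in order; tiers 2 and 3 share a single running
#' counter (continuing after the largest counter of any imported sample),
#' assigned in tier order then sample order. Extracts receive group letters
#' 'A', 'B', 'C', ... in assignment order (wrapping to 'A' after 'Z');
#' test samples inherit the group letter of their parent extract. Checksums
#' are computed per [checksum_char()]. Imported samples (in designs derived
#' from existing ones) keep their identifiers.
#'
#' @param design Unregistered `qd_design`.
#' @return The registered `qd_design`, every sample carrying a valid unique
#'   identifier and explicit parent identifiers.
#' @export
register_design <- function(design) {
  if (!inherits(design, "qd_design"))
    stop("register_design() needs a qd_design", call. = FALSE)
  if (design$registered)
    stop("design is already registered", call. = FALSE)
  project <- design$project
  entity_n <- design$entity_start
  counter <- design$counter_start
  group_idx <- design$group_start

  for (k in 1:3) {
    design$tiers[[k]] <- lapply(design$tiers[[k]], function(s) {
      if (nzchar(s$identifier)) return(s) # imported, keeps its id
      if (k == 1L) {
        entity_n <<- entity_n + 1L
        s$identifier <- make_entity_id(project, entity_n)
      } else {
        counter <<- counter + 1L
        if (counter > 999L)
          stop("sample counter exhausted (>999) for project ", project,
               "; start a new project code", call. = FALSE)
        gc_char <- if (k == 2L) {
          group_idx <<- group_idx + 1L
          LETTERS[(group_idx - 1L) %% 26L + 1L]
        } else {
          parent <- design$tiers[[2L]][[s$parent_index]]
          substr(parent$identifier, 9L, 9L)
        }
        s$identifier <- make_sample_id(project, counter, gc_char)
      }
      s
    })
  }
  # resolve positional parent links into identifiers
  for (k in 2:3) {
    design$tiers[[k]] <- lapply(design$tiers[[k]], function(s) {
      if (!is.na(s$parent_index))
        s$parents <- design$tiers[[k - 1L]][[s$parent_index]]$identifier
      s
    })
  }
  design$registered <- TRUE
  design
}

#' List all samples of a design in table order
#'
#' Table order is tier 1, then 2, then 3, preserving within-tier order.
#'
#' @param design A `qd_design`.
#' @param tiers Tiers to include.
#' @return Flat list of `qd_sample`.
#' @export
design_samples <- function(design, tiers = 1:3) {
  do.call(c, design$tiers[tiers])
}

#' Derive a follow-up design beneath existing registered samples
#'
#' Follow-up experiments reuse samples already registered: new tiers are
#' expanded only beneath the given parents, which keep their identifiers,
#' and inherited factor values are copied into the new samples. The running
#' counter continues after the largest counter seen among the known samples,
#' so identifiers never collide with earlier registrations.
#'
#' @param existing List of registered `qd_sample`, all of the same tier.
#' @param new_tiers List of [tier_spec()] objects for the tiers to add,
#'   starting directly below the parents' tier.
#' @param vocab A `qd_vocabulary` used to resolve tissue/analyte tokens of
#'   the new tiers.
#' @param known Optional list of all registered samples the system knows
#'   (e.g. every sample of an imported design); counters and group letters
#'   continue after their maxima. Defaults to `existing`.
#' @return An unregistered `qd_design` whose parent tier holds the imported
#'   samples; pass to [register_design()] to assign the new identifiers.
#' @export
derive_from_existing <- function(existing, new_tiers,
                                 vocab = load_vocabulary(), known = NULL) {
  if (length(existing) == 0L)
    stop("derive_from_existing() needs at least one existing sample",
         call. = FALSE)
  if (!all(vapply(existing, inherits, TRUE, "qd_sample")))
    stop("existing must be a list of qd_sample", call. = FALSE)
  parent_tiers <- vapply(existing, sample_tier, 0L)
  if (length(unique(parent_tiers)) != 1L)
    stop("existing samples must all be of the same tier", call. = FALSE)
  k0 <- parent_tiers[1L]
  ids <- vapply(existing, `[[`, "", "identifier")
  if (any(!nzchar(ids)))
    stop("existing samples must be registered (have identifiers)",
         call. = FALSE)
  if (inherits(new_tiers, "qd_tier_spec")) new_tiers <- list(new_tiers)
  if (length(new_tiers) == 0L)
    stop("no new tiers to derive", call. = FALSE)
  want <- (k0 + 1L):(k0 + length(new_tiers))
  if (any(want > 3L))
    stop("derived tiers would exceed tier 3", call. = FALSE)
  got <- vapply(new_tiers, `[[`, 0L, "tier")
  if (!identical(got, want))
    stop("new tiers must start directly below tier ", k0,
         " and be contiguous (expected ", paste(want, collapse = ", "),
         ", got ", paste(got, collapse = ", "), ")", call. = FALSE)

  project <- parse_id(ids[1L])$project
  known_ids <- vapply(known %||% existing, `[[`, "", "identifier")

  tiers <- rep(list(list()), 3L)
  # imported parents keep their identifiers and parent id strings, but any
  # positional index from their original design is meaningless here
  tiers[[k0]] <- lapply(existing, function(s) {
    s$parent_index <- NA_integer_
    s
  })
  parents <- existing
  for (i in seq_along(new_tiers)) {
    ts <- new_tiers[[i]]
    k <- ts$tier
    props <- ts$properties
    if (k == 2L) {
      if (is.null(ts$tissue)) stop("tier 2 needs a tissue", call. = FALSE)
      v <- validate_vocab_token("tissues", ts$tissue, vocab)
      if (!v$accepted)
        stop("unknown tissue '", ts$tissue, "'", call. = FALSE)
      props$Q_Primary_Tissue <- v$token
    }
    if (k == 3L) {
      if (is.null(ts$analyte)) stop("tier 3 needs an analyte", call. = FALSE)
      v <- validate_vocab_token("analytes", ts$analyte, vocab)
      if (!v$accepted)
        stop("unknown analyte '", ts$analyte, "'", call. = FALSE)
      props$Q_SAMPLE_TYPE <- v$token
    }
    tiers[[k]] <- expand_tier(parents, ts$factors, ts$replicates,
                              type = QD_SAMPLE_TYPES[k], properties = props)
    parents <- tiers[[k]]
  }
  new_design(project, tiers,
             counter_start = max_sample_counter(known_ids),
             entity_start = max_entity_index(known_ids),
             group_start = max_group_index(known_ids))
}
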