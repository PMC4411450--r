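# The one-sample-per-row TSV exchange format. Dialect: UTF-8, Unix
# newlines, no quoting — tabs and newlines are forbidden inside cells rather
# than escaped, which is what keeps round trips through spreadsheet
# applications byte-exact. Empty string denotes an absent value. The header
# starts with the 8 canonical columns; any further column is a custom
# property.

# cells a spreadsheet row may not contain
assert_cell <- function(x, what) {
  if (grepl("[\t\n\r]", x))
    stop(what, " contains a tab or newline character: '", x, "'",
         call. = FALSE)
  x
}

prop_or_empty <- function(sample, key) {
  v <- sample$properties[[key]]
  if (is.null(v)) "" else as.character(v)
}

custom_prop_names <- function(samples) {
  out <- character(0)
  for (s in samples) {
    extra <- setdiff(names(s$properties), QD_CANONICAL_PROPS)
    out <- c(out, extra[!extra %in% out])
  }
  out
}

#' Serialize a registered design to TSV text
#'
#' One sample per row in table order (tier 1, 2, 3). The 8 canonical columns
#' come first; custom properties, if any sample carries them, are appended
#' as extra columns after XML_FACTORS in first-seen order. Fields that do
#' not apply to a tier stay empty: entities have no Parent, tissue or
#' analyte; extracts carry the tissue but no analyte; test samples the
#' analyte but no tissue. The XML_FACTORS cell holds the condensed factor
#' rendering.
#'
#' @param design Registered `qd_design`.
#' @param path Optional file path; when given, the text is also written
#'   there (UTF-8, Unix newlines).
#' @return The TSV text, invisibly when `path` is given.
#' @export
write_design_tsv <- function(design, path = NULL) {
  if (!inherits(design, "qd_design"))
    stop("write_design_tsv() needs a qd_design", call. = FALSE)
  if (!design$registered)
    stop("design must be registered before export", call. = FALSE)
  samples <- design_samples(design)
  extras <- custom_prop_names(samples)
  header <- c(QD_CANONICAL_COLUMNS, extras)
  lines <- vapply(samples, function(s) {
    cells <- c(s$identifier,
               s$type,
               paste(s$parents, collapse = ","),
               prop_or_empty(s, "Q_Primary_Tissue"),
               prop_or_empty(s, "Q_NCBI_Organism"),
               prop_or_empty(s, "Q_SAMPLE_TYPE"),
               prop_or_empty(s, "Q_EXTERNALDB_ID"),
               to_condensed(s$factor_values),
               vapply(extras, function(e) prop_or_empty(s, e), ""))
    for (cell in cells) assert_cell(cell, paste0("row ", s$identifier))
    paste(cells, collapse = "\t")
  }, "")
  text <- paste0(paste(c(paste(header, collapse = "\t"), lines),
                       collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(enc2utf8(text), con, eos = NULL, useBytes = TRUE)
    return(invisible(text))
  }
  text
}

# split TSV text/file into header + padded cell rows
parse_design_table <- function(x) {
  lines <- if (length(x) == 1L && !grepl("[\t\n]", x) && file.exists(x))
    readLines(x, encoding = "UTF-8", warn = FALSE)
  else
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!(seq_along(lines) == length(lines) & !nzchar(lines))]
  if (length(lines) == 0L)
    stop("empty design table", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < length(QD_CANONICAL_COLUMNS) ||
      !identical(header[seq_along(QD_CANONICAL_COLUMNS)], QD_CANONICAL_COLUMNS))
    stop("unknown column layout: header must begin with the canonical ",
         "columns ", paste(QD_CANONICAL_COLUMNS, collapse = ", "),
         call. = FALSE)
  ncol <- length(header)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(cells) > ncol)
      stop("row ", i - 1L, " has ", length(cells), " cells but the header ",
           "declares ", ncol, " columns", call. = FALSE)
    c(cells, rep("", ncol - length(cells)))
  })
  list(header = header, rows = rows)
}

#' Read a design back from its TSV form
#'
#' Reconstructs samples, tiers (from the Sample type column), parent links,
#' properties and factor values. Every identifier's checksum is recomputed
#' and every Parent reference must name an identifier appearing earlier in
#' the table; violations are reported with their row.
#'
#' @param x TSV text or a file path.
#' @return A registered `qd_design`.
#' @export
read_design_tsv <- function(x) {
  tab <- parse_design_table(x)
  extras <- tab$header[-seq_along(QD_CANONICAL_COLUMNS)]
  tiers <- rep(list(list()), 3L)
  seen <- character(0)       # identifiers in row order
  seen_tier <- integer(0)
  project <- NULL
  for (i in seq_along(tab$rows)) {
    cells <- tab$rows[[i]]
    id <- cells[1L]
    v <- validate_id(id)
    if (!v$valid)
      stop("row ", i, ": invalid identifier '", id, "' (", v$reason, ")",
           call. = FALSE)
    if (id %in% seen)
      stop("row ", i, ": duplicate identifier '", id, "'", call. = FALSE)
    p <- parse_id(id)
    if (is.null(project)) project <- p$project
    else if (p$project != project)
      stop("row ", i, ": identifier '", id, "' belongs to project ",
           p$project, ", expected ", project, call. = FALSE)
    type <- cells[2L]
    tier <- match(type, QD_SAMPLE_TYPES)
    if (is.na(tier))
      stop("row ", i, ": unknown sample type '", type, "'", call. = FALSE)
    parents <- if (nzchar(cells[3L]))
      strsplit(cells[3L], ",", fixed = TRUE)[[1L]] else character(0)
    if (tier == 1L && length(parents) > 0L)
      stop("row ", i, ": a biological entity cannot have a parent",
           call. = FALSE)
    if (tier > 1L && length(parents) == 0L)
      stop("row ", i, ": tier-", tier, " sample '", id, "' has no parent",
           call. = FALSE)
    for (par in parents) {
      j <- match(par, seen)
      if (is.na(j))
        stop("row ", i, ": parent '", par, "' of '", id,
             "' does not appear earlier in the table", call. = FALSE)
      if (seen_tier[j] != tier - 1L)
        stop("row ", i, ": parent '", par, "' of '", id,
             "' is not a tier-", tier - 1L, " sample", call. = FALSE)
    }
    fvals <- tryCatch(from_condensed(cells[8L]), error = function(e)
      stop("row ", i, " (", id, "): bad XML_FACTORS cell: ",
           conditionMessage(e), call. = FALSE))
    props <- list()
    for (ci in seq_along(QD_CANONICAL_PROPS)) {
      val <- cells[3L + ci]
      if (nzchar(val)) props[[QD_CANONICAL_PROPS[ci]]] <- val
    }
    for (ei in seq_along(extras)) {
      val <- cells[length(QD_CANONICAL_COLUMNS) + ei]
      if (nzchar(val)) props[[extras[ei]]] <- val
    }
    parent_index <- if (length(parents) == 1L && tier > 1L) {
      prev_ids <- vapply(tiers[[tier - 1L]], `[[`, "", "identifier")
      match(parents, prev_ids)
    } else NA_integer_
    tiers[[tier]] <- c(tiers[[tier]], list(
      new_sample(type, parent_index = parent_index,
                 factor_values = fvals, properties = props,
                 identifier = id, parents = parents)))
    seen <- c(seen, id)
    seen_tier <- c(seen_tier, tier)
  }
  if (is.null(project))
    stop("design table has no sample rows; cannot infer a project",
         call. = FALSE)
  new_design(project, tiers, registered = TRUE,
             counter_start = max_sample_counter(seen),
             entity_start = max_entity_index(seen),
             group_start = max_group_index(seen))
}

#' Merge a user-edited table back into a design
#'
#' The exported TSV is meant to be filled in or extended by collaborators
#' and reuploaded. Identifier, Sample type and Parent are immutable — they
#' define the registered hierarchy. Non-empty cells of the canonical
#' property columns overwrite the stored values; the XML_FACTORS cell is
#' authoritative (it is parsed and replaces the sample's factor values, an
#' empty cell clearing them); any non-canonical column becomes a custom
#' property on the rows where its cell is non-empty. The merge is
#' idempotent.
#'
#' @param original Registered `qd_design` the table was exported from.
#' @param edited Edited table: TSV text or file path.
#' @return The updated `qd_design`.
#' @export
merge_edits <- function(original, edited) {
  if (!inherits(original, "qd_design") || !original$registered)
    stop("merge_edits() needs the original registered qd_design",
         call. = FALSE)
  tab <- parse_design_table(edited)
  extras <- tab$header[-seq_along(QD_CANONICAL_COLUMNS)]
  ids <- vapply(tab$rows, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("edited table contains duplicate identifier '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  orig_ids <- vapply(design_samples(original), `[[`, "", "identifier")
  if (!setequal(ids, orig_ids)) {
    added <- setdiff(ids, orig_ids)
    removed <- setdiff(orig_ids, ids)
    stop("edited table must contain exactly the registered identifiers",
         if (length(added)) paste0("; unknown: ",
                                   paste(added, collapse = ", ")),
         if (length(removed)) paste0("; missing: ",
                                     paste(removed, collapse = ", ")),
         call. = FALSE)
  }
  row_of <- function(id) tab$rows[[match(id, ids)]]
  for (k in 1:3) {
    original$tiers[[k]] <- lapply(original$tiers[[k]], function(s) {
      cells <- row_of(s$identifier)
      if (cells[2L] != s$type)
        stop("row ", s$identifier, ": Sample type is immutable", call. = FALSE)
      if (cells[3L] != paste(s$parents, collapse = ","))
        stop("row ", s$identifier, ": Parent is immutable", call. = FALSE)
      for (ci in seq_along(QD_CANONICAL_PROPS)) {
        val <- cells[3L + ci]
        if (nzchar(val)) s$properties[[QD_CANONICAL_PROPS[ci]]] <- val
      }
      s$factor_values <- tryCatch(from_condensed(cells[8L]),
        error = function(e) stop("row ", s$identifier,
                                 ": bad XML_FACTORS cell: ",
                                 conditionMessage(e), call. = FALSE))
      for (ei in seq_along(extras)) {
        val <- cells[length(QD_CANONICAL_COLUMNS) + ei]
        if (nzchar(val)) s$properties[[extras[ei]]] <- val
      }
      s
    })
  }
  original
}
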