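# Downstream artifacts: per-lab sample sheets and the MaxQuant
# experimental-design file (the classic experimentalDesignTemplate with
# Name / Fraction / Experiment columns).

tier_label <- c("Biological entity", "Sample extract", "Test sample")

#' Build a lab sample sheet
#'
#' One row per sample of the selected tiers, in table order, carrying
#' everything a wet lab needs to act on the design: the identifier, the
#' human-readable secondary name (if one was set), the tier, the treatment
#' (condensed factor rendering) and the context — the parent sample the
#' material derives from.
#'
#' @param design Registered `qd_design`.
#' @param tiers Non-empty subset of `1:3`.
#' @return A `data.frame` with columns Identifier, Name, Tier, Treatment,
#'   Context.
#' @export
sample_sheet <- function(design, tiers = c(2L, 3L)) {
  if (!inherits(design, "qd_design") || !design$registered)
    stop("sample_sheet() needs a registered qd_design", call. = FALSE)
  tiers <- unique(as.integer(tiers))
  if (length(tiers) == 0L || anyNA(tiers) || !all(tiers %in% 1:3))
    stop("tiers must be a non-empty subset of 1:3", call. = FALSE)
  samples <- design_samples(design, sort(tiers))
  data.frame(
    Identifier = vapply(samples, `[[`, "", "identifier"),
    Name = vapply(samples, prop_or_empty, "", "Q_SECONDARY_NAME"),
    Tier = vapply(samples, function(s) tier_label[sample_tier(s)], ""),
    Treatment = vapply(samples, function(s) to_condensed(s$factor_values), ""),
    Context = vapply(samples, function(s)
      paste(s$parents, collapse = ","), ""),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

#' Write a sample sheet as TSV
#'
#' @param sheet Data frame from [sample_sheet()].
#' @param path Optional output path.
#' @return The TSV text, invisibly when `path` is given.
#' @export
write_sample_sheet <- function(sheet, path = NULL) {
  write_simple_tsv(sheet, path)
}

# strip the extension from a raw file name
file_base_name <- function(filename) sub("\\.[^./\\\\]*$", "", filename)

#' Build a MaxQuant experimental-design table
#'
#' MaxQuant assigns raw MS files to experiments through a tab-separated
#' design file with columns Name, Fraction and Experiment. Name is the raw
#' file name without its extension; Fraction defaults to 1; Experiment
#' groups files that are analysed together while keeping their ratios
#' separate — here, the sample's level of a chosen design factor, or the
#' project code when grouping by `"all"`.
#'
#' @param samples List of registered tier-3 `qd_sample` (e.g.
#'   `design_samples(design, 3)`).
#' @param file_map Named character vector or list, identifier -> raw file
#'   name; every sample must be mapped.
#' @param fractions Optional named integer vector or list, identifier ->
#'   fraction number (>= 1); unmapped samples default to fraction 1.
#' @param group_by Factor label to group by, or `"all"` for a single group
#'   named after the project code.
#' @return A `data.frame` with columns Name, Fraction, Experiment, one row
#'   per sample in input order.
#' @export
maxquant_design <- function(samples, file_map, fractions = NULL,
                            group_by = "all") {
  if (!all(vapply(samples, inherits, TRUE, "qd_sample")))
    stop("samples must be qd_sample objects", call. = FALSE)
  if (!all(vapply(samples, function(s) s$type == "Q_TEST_SAMPLE", TRUE)))
    stop("MaxQuant export takes tier-3 test samples only", call. = FALSE)
  ids <- vapply(samples, `[[`, "", "identifier")
  if (any(!nzchar(ids)))
    stop("samples must be registered", call. = FALSE)
  file_map <- unlist(file_map)
  missing <- setdiff(ids, names(file_map))
  if (length(missing) > 0L)
    stop("no raw file mapped for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fractions <- unlist(fractions)
  name <- file_base_name(unname(file_map[ids]))
  if (anyDuplicated(name))
    stop("duplicate Name after stripping extensions: '",
         name[duplicated(name)][1L], "'", call. = FALSE)
  fraction <- vapply(ids, function(id) {
    f <- if (id %in% names(fractions)) as.integer(fractions[[id]]) else 1L
    if (is.na(f) || f < 1L)
      stop("fraction for ", id, " must be a positive integer", call. = FALSE)
    f
  }, 0L)
  experiment <- if (identical(group_by, "all")) {
    vapply(ids, function(id) parse_id(id)$project, "")
  } else {
    vapply(samples, function(s) {
      labs <- vapply(s$factor_values, `[[`, "", "label")
      j <- match(group_by, labs)
      if (is.na(j))
        stop("sample ", s$identifier, " has no factor '", group_by, "'",
             call. = FALSE)
      v <- s$factor_values[[j]]
      if (is.numeric(v$value)) paste0(num_str(v$value), " ", v$unit)
      else v$value
    }, "")
  }
  data.frame(Name = name, Fraction = unname(fraction),
             Experiment = unname(experiment),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a MaxQuant design table to its tab-separated file form
#'
#' @param mq Data frame from [maxquant_design()].
#' @param path Optional output path.
#' @return The text, invisibly when `path` is given.
#' @export
write_maxquant <- function(mq, path = NULL) {
  write_simple_tsv(mq, path)
}

# header + rows, tab-separated, Unix newlines, no quoting
write_simple_tsv <- function(df, path = NULL) {
  cells <- vapply(df, as.character, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0L) apply(cells, 1L, paste, collapse = "\t"))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(enc2utf8(text), con, eos = NULL, useBytes = TRUE)
    return(invisible(text))
  }
  text
}
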