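# Controlled vocabularies: organisms (NCBI taxonomy ids), tissues, analytes.
# Small bundled plain-text files, overridable per call; lookups are total
# and deterministic.

qd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "qdesign")
  if (!nzchar(path))
    stop("bundled data file '", file, "' not found", call. = FALSE)
  path
}

read_token_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Load the controlled vocabularies
#'
#' Reads the organism, tissue and analyte vocabularies from plain-text
#' files. Defaults to the small tables bundled with the package; any of the
#' three can be overridden with a file of the same shape (taxa:
#' `name<TAB>id` per line; tissues/analytes: one token per line; `#` starts
#' a comment).
#'
#' @param taxa,tissues,analytes Optional paths overriding the bundled files.
#' @return An object of class `qd_vocabulary` with elements `taxa` (named
#'   integer vector), `tissues` and `analytes` (character vectors of
#'   canonical tokens).
#' @export
load_vocabulary <- function(taxa = NULL, tissues = NULL, analytes = NULL) {
  taxa_lines <- read_token_file(taxa %||% qd_extdata("taxa.tsv"))
  parts <- strsplit(taxa_lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed taxa vocabulary line: '", taxa_lines[which(bad)[1]], "'",
         call. = FALSE)
  ids <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(ids) || any(ids <= 0L))
    stop("taxa vocabulary ids must be positive integers", call. = FALSE)
  names(ids) <- vapply(parts, `[`, "", 1L)
  structure(list(
    taxa = ids,
    tissues = read_token_file(tissues %||% qd_extdata("tissues.txt")),
    analytes = read_token_file(analytes %||% qd_extdata("analytes.txt"))
  ), class = "qd_vocabulary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

closest_tokens <- function(token, known, n = 3L) {
  d <- utils::adist(tolower(token), tolower(known))[1L, ]
  known[order(d)][seq_len(min(n, length(known)))]
}

#' Resolve an organism to its NCBI taxonomy id
#'
#' Names and aliases are matched case-insensitively against the vocabulary;
#' a decimal integer string is passed through after a positivity check, so
#' ids outside the bundled vocabulary remain usable.
#'
#' @param name_or_id Organism name, alias, or decimal integer string.
#' @param vocab A `qd_vocabulary`, by default the bundled one.
#' @return The taxonomy id as an integer.
#' @examples
#' resolve_taxon("Gallus gallus") # 9031
#' resolve_taxon("9031")          # 9031
#' @export
resolve_taxon <- function(name_or_id, vocab = load_vocabulary()) {
  x <- trimws(as.character(name_or_id))
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop("resolve_taxon(): need a single organism name or id", call. = FALSE)
  if (grepl("^[0-9]+$", x)) {
    id <- as.integer(x)
    if (is.na(id) || id <= 0L)
      stop("taxonomy id must be a positive integer, got '", x, "'", call. = FALSE)
    return(id)
  }
  hit <- match(tolower(x), tolower(names(vocab$taxa)))
  if (is.na(hit))
    stop("unknown organism '", x, "'; closest known entries: ",
         paste(closest_tokens(x, names(vocab$taxa)), collapse = ", "),
         call. = FALSE)
  unname(vocab$taxa[hit])
}

#' Validate a tissue or analyte token
#'
#' Matching is case-insensitive; the verdict carries the canonical casing so
#' inconsistently-cased lab spreadsheets normalize on import.
#'
#' @param kind `"tissues"` or `"analytes"`.
#' @param token Candidate token.
#' @param vocab A `qd_vocabulary`.
#' @return List with `accepted` (logical), `token` (canonical form, or `NA`
#'   if rejected) and `suggestions` (closest known tokens when rejected).
#' @export
validate_vocab_token <- function(kind, token, vocab = load_vocabulary()) {
  if (!kind %in% c("tissues", "analytes"))
    stop("unknown vocabulary kind '", kind, "'; use 'tissues' or 'analytes'",
         call. = FALSE)
  known <- vocab[[kind]]
  hit <- match(tolower(trimws(token)), tolower(known))
  if (is.na(hit))
    list(accepted = FALSE, token = NA_character_,
         suggestions = closest_tokens(token, known))
  else
    list(accepted = TRUE, token = known[hit], suggestions = character(0))
}

#' @export
print.qd_vocabulary <- function(x, ...) {
  cat("qdesign vocabulary:", length(x$taxa), "organism entries,",
      length(x$tissues), "tissues,", length(x$analytes), "analytes\n")
  invisible(x)
}
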