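# Project-scoped sample identifiers with a weighted checksum character.
#
# Two grammars:
#   sample form:  <project(5)><counter(3 digits)><group letter><checksum>
#   entity form:  <project(5)>ENTITY-<n>
# The checksum character is computed from the first nine characters and
# detects single-character transcription errors.

#' Compute the weighted checksum character of an identifier stem
#'
#' The checksum is the weighted sum of the ASCII codes of the stem, each
#' code multiplied by its 1-based position, taken modulo 34 and mapped to
#' the 34-character alphabet `0`-`9`, `A`-`X`. Appending the returned
#' character to a 9-character sample-identifier stem yields the full
#' 10-character identifier.
#'
#' @param stem Non-empty ASCII string (for sample identifiers, the first
#'   nine characters: project code, counter, group letter).
#' @return Single checksum character.
#' @examples
#' checksum_char("QMELA001A") # "K"
#' @export
checksum_char <- function(stem) {
  if (!is.character(stem) || length(stem) != 1L || is.na(stem) || !nzchar(stem))
    stop("checksum_char(): stem must be a single non-empty string", call. = FALSE)
  codes <- utf8ToInt(stem)
  if (any(codes > 127L))
    stop("checksum_char(): stem must be ASCII", call. = FALSE)
  s <- sum(codes * seq_along(codes)) %% 34L
  if (s < 10L) intToUtf8(48L + s) else intToUtf8(55L + s)
}

# internal: project-code grammar check
is_project_code <- function(code) {
  is.character(code) && length(code) == 1L && !is.na(code) &&
    grepl("^Q[A-Z0-9]{4}$", code)
}

assert_project_code <- function(code) {
  if (!is_project_code(code))
    stop("invalid project code '", code,
         "': must be 5 characters, 'Q' followed by uppercase alphanumerics",
         call. = FALSE)
  code
}

#' Build a checksummed 10-character sample identifier
#'
#' @param project 5-character project code ('Q' + 4 uppercase alphanumerics).
#' @param counter Integer 1--999; zero-padded to three digits. Counters are
#'   fixed-width: a project holds at most 999 extract/test samples, and
#'   exceeding that is an error (start a new project code).
#' @param group_char Single uppercase letter (9th character). Extracts
#'   receive sequential letters at registration; test samples inherit their
#'   parent's letter.
#' @return The 10-character identifier string.
#' @examples
#' make_sample_id("QMELA", 1, "A") # "QMELA001AK"
#' @export
make_sample_id <- function(project, counter, group_char) {
  assert_project_code(project)
  counter <- as.integer(counter)
  if (is.na(counter) || counter < 1L || counter > 999L)
    stop("sample counter ", counter, " out of range 1-999; ",
         "the 3-digit counter is exhausted - start a new project code",
         call. = FALSE)
  if (!grepl("^[A-Z]$", group_char))
    stop("group_char must be a single uppercase letter, got '", group_char, "'",
         call. = FALSE)
  stem <- sprintf("%s%03d%s", project, counter, group_char)
  paste0(stem, checksum_char(stem))
}

#' Build an entity identifier
#'
#' Tier-1 biological entities carry `<project>ENTITY-<n>` identifiers with
#' no padding and no checksum.
#'
#' @param project 5-character project code.
#' @param index Positive integer.
#' @return Identifier string, e.g. `"QMELAENTITY-1"`.
#' @export
make_entity_id <- function(project, index) {
  assert_project_code(project)
  index <- as.integer(index)
  if (is.na(index) || index < 1L)
    stop("entity index must be >= 1, got ", index, call. = FALSE)
  paste0(project, "ENTITY-", index)
}

#' Validate a candidate identifier
#'
#' Total function: never errors. A 10-character candidate is checked against
#' the sample grammar and its checksum is recomputed; other candidates are
#' checked against the entity grammar.
#'
#' @param candidate Character string.
#' @return A list with `valid` (logical), `form` (`"sample"`, `"entity"` or
#'   `NA`), and `reason` (`NA` when valid, otherwise one of `"bad-length"`,
#'   `"bad-grammar"`, `"bad-checksum"`).
#' @examples
#' validate_id("QMELA011DK")$valid    # TRUE
#' validate_id("QMELA011DL")$reason   # "bad-checksum"
#' @export
validate_id <- function(candidate) {
  bad <- function(reason) list(valid = FALSE, form = NA_character_, reason = reason)
  if (!is.character(candidate) || length(candidate) != 1L || is.na(candidate))
    return(bad("bad-length"))
  if (nchar(candidate) == 10L) {
    if (!grepl("^Q[A-Z0-9]{4}[0-9]{3}[A-Z][0-9A-X]$", candidate))
      return(bad("bad-grammar"))
    if (substr(candidate, 10L, 10L) != checksum_char(substr(candidate, 1L, 9L)))
      return(bad("bad-checksum"))
    return(list(valid = TRUE, form = "sample", reason = NA_character_))
  }
  if (grepl("ENTITY-", candidate, fixed = TRUE)) {
    if (grepl("^Q[A-Z0-9]{4}ENTITY-[1-9][0-9]*$", candidate))
      return(list(valid = TRUE, form = "entity", reason = NA_character_))
    return(bad("bad-grammar"))
  }
  bad("bad-length")
}

#' Parse a valid identifier into its parts
#'
#' @param candidate Identifier string; must validate under [validate_id()].
#' @return For the sample form, a list with `form = "sample"`, `project`,
#'   `counter`, `group_char`, `checksum`; for the entity form, a list with
#'   `form = "entity"`, `project`, `entity_index`.
#' @export
parse_id <- function(candidate) {
  v <- validate_id(candidate)
  if (!v$valid)
    stop("invalid identifier '", candidate, "' (", v$reason, ")", call. = FALSE)
  if (v$form == "sample") {
    list(form = "sample",
         project = substr(candidate, 1L, 5L),
         counter = as.integer(substr(candidate, 6L, 8L)),
         group_char = substr(candidate, 9L, 9L),
         checksum = substr(candidate, 10L, 10L))
  } else {
    list(form = "entity",
         project = substr(candidate, 1L, 5L),
         entity_index = as.integer(sub("^.*ENTITY-", "", candidate)))
  }
}

#' Scan a file name for embedded sample identifiers
#'
#' Slides a 10-character window over the string and collects every substring
#' that validates as a sample identifier (grammar plus checksum); the
#' checksum makes accidental matches rare, so no delimiter convention is
#' assumed. Raw-data files named after their sample can thereby be linked
#' back to the design.
#'
#' @param filename Character string (a file name or path).
#' @return Character vector of valid sample identifiers, in order of first
#'   occurrence, de-duplicated; empty when none found.
#' @examples
#' scan_filename("QMELA005AI_run1.raw")
#' @export
scan_filename <- function(filename) {
  if (!is.character(filename) || length(filename) != 1L || is.na(filename))
    return(character(0))
  n <- nchar(filename)
  if (n < 10L) return(character(0))
  hits <- character(0)
  for (i in seq_len(n - 9L)) {
    cand <- substr(filename, i, i + 9L)
    if (validate_id(cand)$valid) hits <- c(hits, cand)
  }
  unique(hits)
}
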