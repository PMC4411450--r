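# Experimental factors and factor values, with two serializations:
#  - an XML document (<qfactors> with <qcategorical>/<qcontinuous> children,
#    validated against the shipped qfactors.xsd), the authoritative form;
#  - the condensed "label: value; label: value unit" text used in the TSV's
#    XML_FACTORS column, a presentational projection of the same data.

si_unit_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_token_file(qd_extdata("si_units.txt"))
    cache
  }
})

#' List the accepted SI unit tokens
#' @return Character vector of unit tokens (base units plus prefixed forms).
#' @export
si_units <- function() si_unit_table()

#' Validate an SI unit token
#'
#' Continuous factor values must carry a unit from the shipped table
#' (the seven SI base units plus prefixed gram/litre/mole/molar/metre/second
#' forms). Matching is case-sensitive: `"mM"` and `"MM"` differ.
#'
#' @param token Candidate unit token.
#' @return `TRUE` or `FALSE`.
#' @export
validate_unit <- function(token) {
  is.character(token) && length(token) == 1L && !is.na(token) &&
    token %in% si_unit_table()
}

# render a numeric factor value without scientific notation
num_str <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

#' Define an experimental factor
#'
#' A factor is one experimental variable with its ordered set of levels.
#' Categorical factors take character levels; continuous factors take
#' numeric levels and exactly one SI unit.
#'
#' @param label Factor name, free text (no `:` or `;`, which the condensed
#'   rendering reserves).
#' @param levels Character vector (categorical) or numeric vector
#'   (continuous) of distinct level values, at least one.
#' @param unit SI unit token; required for numeric levels, forbidden
#'   otherwise.
#' @return Object of class `qd_factor`.
#' @examples
#' factor_def("Phenotype", c("black", "yellow"))
#' factor_def("dose", c(5, 10), unit = "mg")
#' @export
factor_def <- function(label, levels, unit = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label)))
    stop("factor label must be a non-empty string", call. = FALSE)
  if (grepl("[:;\t\n]", label))
    stop("factor label '", label, "' may not contain ':', ';', tab or newline",
         call. = FALSE)
  if (length(levels) < 1L)
    stop("factor '", label, "' needs at least one level", call. = FALSE)
  if (anyDuplicated(levels))
    stop("factor '", label, "' has duplicate levels", call. = FALSE)
  continuous <- is.numeric(levels)
  if (continuous) {
    if (is.null(unit) || !validate_unit(unit))
      stop("continuous factor '", label, "' needs a valid SI unit",
           if (!is.null(unit)) paste0("; '", unit, "' is not in the unit table"),
           call. = FALSE)
  } else {
    levels <- as.character(levels)
    if (any(grepl("[:;\t\n]", levels)))
      stop("levels of '", label, "' may not contain ':', ';', tab or newline",
           call. = FALSE)
    if (!is.null(unit))
      stop("categorical factor '", label, "' must not carry a unit", call. = FALSE)
  }
  structure(list(label = label,
                 kind = if (continuous) "continuous" else "categorical",
                 levels = levels,
                 unit = if (continuous) unit else NULL),
            class = "qd_factor")
}

#' Create a single factor value (one label/value pair)
#'
#' @param label Factor name.
#' @param value Character (categorical) or numeric (continuous) value.
#' @param unit SI unit token, required iff `value` is numeric.
#' @return Object of class `qd_factor_value`.
#' @export
factor_value <- function(label, value, unit = "") {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label)))
    stop("factor value label must be a non-empty string", call. = FALSE)
  continuous <- is.numeric(value)
  if (continuous) {
    if (!nzchar(unit))
      stop("numeric factor value '", label, "' needs a unit", call. = FALSE)
    if (!validate_unit(unit))
      stop("'", unit, "' is not an accepted SI unit token", call. = FALSE)
  } else {
    value <- as.character(value)
    if (nzchar(unit))
      stop("categorical factor value '", label, "' must not carry a unit",
           call. = FALSE)
    if (!nzchar(trimws(value)))
      stop("factor value for '", label, "' is empty", call. = FALSE)
  }
  structure(list(label = label, value = value, unit = unit),
            class = "qd_factor_value")
}

#' @export
format.qd_factor_value <- function(x, ...) {
  if (is.numeric(x$value)) paste0(x$label, ": ", num_str(x$value), " ", x$unit)
  else paste0(x$label, ": ", x$value)
}

#' @export
print.qd_factor_value <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

assert_unique_labels <- function(values) {
  labs <- vapply(values, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("duplicate factor label '", labs[duplicated(labs)][1L], "'",
         call. = FALSE)
  labs
}

#' Render factor values in the condensed text form
#'
#' Pairs are joined as `label: value` (continuous values as
#' `label: value unit`), separated by `"; "`, in input order. This is the
#' form the TSV's XML_FACTORS column carries; it is presentational — a
#' categorical value that happens to look like `<number> <unit>` is
#' indistinguishable from a continuous one, so the XML form stays
#' authoritative.
#'
#' @param values List of `qd_factor_value`.
#' @return A single string; `""` for an empty list.
#' @examples
#' to_condensed(list(factor_value("Phenotype", "black")))
#' @export
to_condensed <- function(values) {
  if (length(values) == 0L) return("")
  for (v in values) {
    if (grepl("[:;]", v$label) || (!is.numeric(v$value) && grepl("[:;]", v$value)))
      stop("condensed form forbids ':' and ';' in labels and values (", v$label,
           ")", call. = FALSE)
  }
  paste(vapply(values, format, ""), collapse = "; ")
}

#' Parse the condensed factor text form
#'
#' Inverse of [to_condensed()]. Pairs are split on `";"`, each pair on its
#' first `":"`; surrounding whitespace is tolerated. A value of the shape
#' `<number> <unit>` whose trailing token is an accepted SI unit is read as
#' continuous; anything else is categorical (so `"tyrosin-"` stays a plain
#' categorical level).
#'
#' @param text Condensed string, possibly empty.
#' @return List of `qd_factor_value` in text order.
#' @examples
#' from_condensed("Phenotype: yellow; growth medium: tyrosin-")
#' @export
from_condensed <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("from_condensed(): need a single string", call. = FALSE)
  if (!nzchar(trimws(text))) return(list())
  pairs <- strsplit(text, ";", fixed = TRUE)[[1L]]
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    colon <- regexpr(":", p, fixed = TRUE)
    if (colon < 0L)
      stop("pair ", i, " ('", trimws(p), "') has no ':' separator", call. = FALSE)
    label <- trimws(substr(p, 1L, colon - 1L))
    value <- trimws(substr(p, colon + 1L, nchar(p)))
    if (!nzchar(label))
      stop("pair ", i, " has an empty label", call. = FALSE)
    if (!nzchar(value))
      stop("pair ", i, " ('", label, "') has an empty value", call. = FALSE)
    m <- regmatches(value, regexec("^([+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?) (\\S+)$", value))[[1L]]
    if (length(m) == 4L && validate_unit(m[4L]))
      out[[i]] <- factor_value(label, as.numeric(m[2L]), m[4L])
    else
      out[[i]] <- factor_value(label, value)
  }
  out
}

qfactors_schema <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- xml2::read_xml(qd_extdata("qfactors.xsd"))
    cache
  }
})

#' Serialize factor values to the qfactors XML document
#'
#' Builds a `<qfactors>` document with one `<qcategorical label value>` or
#' `<qcontinuous label value unit>` child per value, in input order, and
#' validates it against the shipped XML Schema (`qfactors.xsd`) before
#' returning. Labels must be unique within a document; continuous units must
#' be accepted SI tokens.
#'
#' @param values List of `qd_factor_value`.
#' @return An `xml2::xml_document`.
#' @examples
#' as.character(factors_to_xml(list(factor_value("Phenotype", "black"))))
#' @export
factors_to_xml <- function(values) {
  assert_unique_labels(values)
  doc <- xml2::xml_new_root("qfactors")
  for (v in values) {
    if (is.numeric(v$value)) {
      if (!validate_unit(v$unit))
        stop("'", v$unit, "' is not an accepted SI unit token", call. = FALSE)
      xml2::xml_add_child(doc, "qcontinuous", label = v$label,
                          value = num_str(v$value), unit = v$unit)
    } else {
      xml2::xml_add_child(doc, "qcategorical", label = v$label, value = v$value)
    }
  }
  stopifnot(xml2::xml_validate(doc, qfactors_schema()))
  doc
}

#' Parse a qfactors XML document into factor values
#'
#' Inverse of [factors_to_xml()]. The document is validated against the
#' shipped schema before any value is returned; semantic checks (unit-table
#' membership, label uniqueness) reject documents the schema alone cannot.
#'
#' @param document An `xml2::xml_document`, an XML string, or a file path.
#' @return List of `qd_factor_value` in document order.
#' @export
factors_from_xml <- function(document) {
  doc <- if (inherits(document, "xml_document")) document
         else tryCatch(xml2::read_xml(document),
                       error = function(e) stop("malformed XML: ",
                                                conditionMessage(e), call. = FALSE))
  ok <- xml2::xml_validate(doc, qfactors_schema())
  if (!isTRUE(ok))
    stop("document does not validate against the qfactors schema: ",
         paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
  kids <- xml2::xml_children(doc)
  out <- vector("list", length(kids))
  for (i in seq_along(kids)) {
    k <- kids[[i]]
    label <- xml2::xml_attr(k, "label")
    if (xml2::xml_name(k) == "qcontinuous") {
      unit <- xml2::xml_attr(k, "unit")
      if (!validate_unit(unit))
        stop("element ", i, " ('", label, "'): unit '", unit,
             "' is not an accepted SI unit token", call. = FALSE)
      out[[i]] <- factor_value(label, as.numeric(xml2::xml_attr(k, "value")), unit)
    } else {
      out[[i]] <- factor_value(label, xml2::xml_attr(k, "value"))
    }
  }
  assert_unique_labels(out)
  out
}
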