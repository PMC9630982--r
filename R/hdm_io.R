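# Reading and writing Demes documents in their human-written form.
#
# A "document" here is the unresolved tree exactly as the author wrote it:
# a named list of scalars, sequences (unnamed lists) and mappings (named
# lists), with no defaults applied and no fields invented. Resolution into
# the fully explicit graph happens separately (see demes_resolve).

# Field names whose values are sequences in the Demes schema. Used to keep
# single-element flow sequences ("ancestors: [A]") as lists.
SEQ_FIELDS <- c("demes", "epochs", "migrations", "pulses", "ancestors",
                "proportions", "sources")
# Time-typed fields: the JSON dialect spells infinity as the string
# "Infinity", which is coerced on load only in these positions.
TIME_FIELDS <- c("start_time", "end_time", "time")

yaml_handlers <- list(
  seq = function(x) x,
  map = function(x) x,
  # YAML 1.1 would read y/n/yes/no/on/off as booleans; the Demes schema has
  # no boolean fields and deme names like "Y" must stay strings.
  "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
  "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x
)

# Reject YAML features outside the safe subset (tags, anchors/aliases,
# multi-document streams) with a lexical scan. Quoted strings and comments
# are stripped first so that e.g. a description containing "&" passes.
check_yaml_subset <- function(text) {
  stripped <- gsub("'[^']*'", "''", text)
  stripped <- gsub('"[^"]*"', '""', stripped)
  lines <- strsplit(stripped, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", lines)
  body <- paste(lines, collapse = "\n")
  if (grepl("(^|[[:space:],{\\[])[&*][A-Za-z0-9_]", body))
    stop("YAML anchors and aliases are not supported", call. = FALSE)
  if (grepl("(^|[[:space:],{\\[])![A-Za-z!<]", body))
    stop("YAML tags are not supported", call. = FALSE)
  if (grepl("\n---", paste0("\n", body)) || grepl("\n\\.\\.\\.", body))
    stop("multi-document YAML streams are not supported", call. = FALSE)
  invisible(TRUE)
}

check_no_dup_names <- function(x, path, where) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      dup <- nm[duplicated(nm)]
      if (length(dup))
        stop(sprintf("duplicate key '%s' at %s", dup[[1]], path), call. = FALSE)
    }
    for (i in seq_along(x)) {
      key <- if (is.null(nm) || nm[i] == "") i else nm[i]
      check_no_dup_names(x[[i]], path_str(path, key), where)
    }
  }
  invisible(TRUE)
}

# Canonicalise a parsed tree: atomic vectors become lists-of-scalars in
# sequence-typed fields; "Infinity"/".inf" strings become +Inf in time
# fields; NaN is rejected anywhere.
canonicalise <- function(x, field = "") {
  if (is.list(x)) {
    nm <- names(x)
    out <- vector("list", length(x))
    for (i in seq_along(x)) {
      f <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else field
      out[[i]] <- canonicalise(x[[i]], f)
    }
    names(out) <- nm
    return(out)
  }
  if (length(x) > 1L || field %in% SEQ_FIELDS && !is.null(x)) {
    # a bare scalar under a sequence field is not auto-wrapped; only true
    # sequences arrive here as length > 1 vectors or lists
  }
  if (length(x) > 1L) return(lapply(seq_along(x), function(i) canonicalise(x[[i]], field)))
  if (is.numeric(x) && length(x) == 1L && is.nan(x))
    stop("NaN is not a permitted value", call. = FALSE)
  if (field %in% TIME_FIELDS && is_string(x) &&
      x %in% c("Infinity", ".inf", "inf"))
    return(Inf)
  x
}

#' Load a Demes document
#'
#' Parses the human-written Demes form from YAML or JSON text into an
#' unresolved document tree (named list). No defaults are applied and no
#' fields are filled in; use [demes_resolve()] to obtain the explicit graph.
#'
#' The YAML scalar `.inf` and, in time-valued fields, the JSON string
#' `"Infinity"` both map to `Inf`. Duplicate mapping keys are rejected, as
#' are YAML anchors, aliases, tags and multi-document streams.
#'
#' @param text a single string containing the document, or a length-one
#'   path readable by [readLines()] when `file = TRUE`.
#' @param dialect `"yaml"` or `"json"`.
#' @param file if `TRUE`, `text` is a file path.
#' @return The document tree: a named list of scalars, lists and mappings.
#' @examples
#' doc <- demes_load("time_units: generations\ndemes:\n- name: a\n  epochs:\n  - start_size: 100")
#' names(doc)
#' @export
demes_load <- function(text, dialect = c("yaml", "json"), file = FALSE) {
  dialect <- match.arg(dialect)
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  stopifnot(is_string(text))
  if (dialect == "yaml") {
    check_yaml_subset(text)
    doc <- tryCatch(
      yaml::yaml.load(text, handlers = yaml_handlers),
      error = function(e) stop(sprintf("YAML syntax error: %s",
                                       conditionMessage(e)), call. = FALSE)
    )
  } else {
    doc <- tryCatch(
      jsonlite::parse_json(text, simplifyVector = FALSE),
      error = function(e) stop(sprintf("JSON syntax error: %s",
                                       conditionMessage(e)), call. = FALSE)
    )
    check_no_dup_names(doc, "$", "json")
  }
  if (!is.list(doc) || is.null(names(doc)))
    stop("document root must be a mapping", call. = FALSE)
  check_no_dup_names(doc, "$", dialect)
  canonicalise(doc)
}

# Prepare a tree for emission: Inf becomes ".inf" (handled natively by the
# yaml emitter) or the string "Infinity" for JSON.
infinity_to_string <- function(x) {
  if (is.list(x)) return(lapply(x, infinity_to_string))
  if (is.numeric(x) && length(x) == 1L && is.infinite(x) && x > 0)
    return("Infinity")
  x
}

#' Serialise a Demes document
#'
#' Inverse of [demes_load()]: `demes_load(demes_dump(doc))` reproduces
#' `doc` up to value-level equality. Infinity is rendered as `.inf` in YAML
#' and as the string `"Infinity"` in JSON.
#'
#' @param doc a document tree as produced by [demes_load()] or
#'   [demes_simplify()].
#' @inheritParams demes_load
#' @return A single string.
#' @export
demes_dump <- function(doc, dialect = c("yaml", "json")) {
  dialect <- match.arg(dialect)
  if (!is.list(doc) || is.null(names(doc)))
    stop("document root must be a mapping", call. = FALSE)
  ok <- rapply(doc, function(v)
    is.null(v) || is.character(v) || is.numeric(v) || is.logical(v),
    how = "unlist")
  if (!all(ok)) stop("document contains non-serialisable nodes", call. = FALSE)
  if (dialect == "yaml") {
    yaml::as.yaml(doc, precision = 22)
  } else {
    as.character(jsonlite::toJSON(infinity_to_string(doc), auto_unbox = TRUE,
                                  digits = I(17), null = "null",
                                  pretty = TRUE))
  }
}

#' Value-level equality of two document trees
#'
#' Compares two unresolved documents structurally. Numbers compare by value
#' (`1L` equals `1.0`), an unnamed list of scalars equals the corresponding
#' atomic vector, and mapping key order is significant only for presence,
#' not position.
#'
#' @param a,b document trees.
#' @return `TRUE` or `FALSE`.
#' @export
demes_doc_equal <- function(a, b) {
  as_cells <- function(x) if (is.list(x)) x else as.list(x)
  if (is.numeric(a) && is.numeric(b) && length(a) == 1L && length(b) == 1L)
    return(isTRUE(a == b) || (is.infinite(a) && is.infinite(b) && sign(a) == sign(b)))
  la <- is.list(a) || length(a) > 1L
  lb <- is.list(b) || length(b) > 1L
  if (la != lb) {
    # one side is a length-1 sequence, the other its bare scalar
    if (la && is.null(names(a)) && length(a) == 1L) return(demes_doc_equal(a[[1]], b))
    if (lb && is.null(names(b)) && length(b) == 1L) return(demes_doc_equal(a, b[[1]]))
    return(FALSE)
  }
  if (!la) return(identical(as.character(a), as.character(b)) ||
                  identical(a, b))
  a <- as_cells(a); b <- as_cells(b)
  if (length(a) != length(b)) return(FALSE)
  na <- names(a); nb <- names(b)
  if (is.null(na) != is.null(nb)) {
    if (length(a) == 0L) return(TRUE)  # empty mapping vs empty sequence
    return(FALSE)
  }
  if (!is.null(na)) {
    if (!setequal(na, nb) || anyDuplicated(na) || anyDuplicated(nb)) return(FALSE)
    b <- b[na]
  }
  for (i in seq_along(a)) if (!demes_doc_equal(a[[i]], b[[i]])) return(FALSE)
  TRUE
}
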