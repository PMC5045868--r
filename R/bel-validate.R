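# Syntax/semantic validation of BEL expressions against a namespace catalog.
#
# Diagnostics are the return value (a data.frame), never thrown. Severity
# "error" marks a statement invalid; "warning" flags curation issues such as
# the artificial placeholder entity, which the scorer tolerates but the
# BELScript exporter refuses.
#
# Error codes:
#   SYNTAX               input failed to parse (text-level validation only)
#   UNKNOWN_NAMESPACE    namespace symbol absent from the catalog
#   UNKNOWN_VALUE        value absent from a known namespace
#   FUNCTION_CLASS_MISMATCH  abundance function incompatible with the
#                        concept's entity class (e.g. p() over a chemical)
#   CONTEXT_CLASS        context-annotation concept (anatomy, cell line,
#                        disease, ...) used inside a statement
# Warning codes:
#   PLACEHOLDER          a PH:placeholder term is present

diag_frame <- function(severity = character(0), code = character(0),
                       message = character(0), start = integer(0),
                       end = integer(0)) {
  data.frame(severity = severity, code = code, message = message,
             start = start, end = end, stringsAsFactors = FALSE)
}

diag_row <- function(severity, code, message, start = NA_integer_,
                     end = NA_integer_) {
  diag_frame(severity, code, message, as.integer(start), as.integer(end))
}

#' Validation configuration
#'
#' The compatibility matrix maps entity classes onto the abundance or wrapper
#' functions their concepts may appear under: chemicals only under `a()`;
#' genes/proteins and families under `a()`, `p()`, `r()`; named complexes
#' under `complex()`; biological processes under `bp()`; cell structures only
#' as `tloc()` targets (pseudo-function `"tloc_loc"`). Anatomy, cell-line and
#' disease concepts belong in context annotations, not inside statements;
#' disease use can be enabled with `allow_disease = TRUE`.
#'
#' @param class_functions Named list: entity class -> allowed function
#'   symbols.
#' @param allow_disease Permit MESHD disease concepts inside statements
#'   (under `a()`).
#' @return A list of class `bel_validate_config`.
#' @export
bel_validate_config <- function(class_functions = NULL,
                                allow_disease = FALSE) {
  if (is.null(class_functions)) {
    class_functions <- list(
      chemical = "a",
      gene_protein = c("a", "p", "r"),
      family = c("a", "p", "r"),
      complex = "complex",
      bioprocess = "bp",
      cell_structure = "tloc_loc",
      anatomy = character(0),
      cell_line = character(0),
      disease = if (allow_disease) "a" else character(0))
  }
  structure(list(class_functions = class_functions,
                 allow_disease = allow_disease),
            class = "bel_validate_config")
}

.node_pos <- function(node) {
  p <- attr(node, "pos")
  if (is.null(p)) NA_integer_ else as.integer(p)
}

.validate_concept <- function(ns, value, context_fn, vocab, config, pos) {
  if (ns == "PH")
    return(diag_row("warning", "PLACEHOLDER",
                    "placeholder entity PH:placeholder must be replaced by a real subject before export",
                    pos))
  if (!ns %in% dict_namespaces(vocab))
    return(diag_row("error", "UNKNOWN_NAMESPACE",
                    sprintf("unknown namespace %s", ns), pos))
  if (!dict_has_value(vocab, ns, value))
    return(diag_row("error", "UNKNOWN_VALUE",
                    sprintf("unknown value in namespace %s: \"%s\"", ns, value),
                    pos))
  cls <- dict_entity_class(vocab, ns, value)
  allowed <- config$class_functions[[cls]]
  if (is.null(allowed)) allowed <- character(0)
  if (length(allowed) == 0L)
    return(diag_row("error", "CONTEXT_CLASS",
                    sprintf("%s concept %s:%s may not appear inside a statement",
                            cls, ns, value), pos))
  if (!context_fn %in% allowed)
    return(diag_row("error", "FUNCTION_CLASS_MISMATCH",
                    sprintf("%s() is not a valid function for %s concept %s:%s",
                            context_fn, cls, ns, value), pos))
  diag_frame()
}

.validate_term <- function(t, vocab, config) {
  pos <- .node_pos(t)
  out <- list()
  if (is_entity_term(t)) {
    out[[length(out) + 1L]] <-
      .validate_concept(t$ns, t$value, t$fn, vocab, config, pos)
  } else {
    if (t$fn == "tloc" && !is.null(t$loc))
      out[[length(out) + 1L]] <-
        .validate_concept(t$loc$ns, t$loc$value, "tloc_loc", vocab, config, pos)
    for (a in t$args)
      out[[length(out) + 1L]] <- .validate_term(a, vocab, config)
  }
  do.call(rbind, c(list(diag_frame()), out))
}

#' Validate a BEL term or statement against a namespace catalog
#'
#' @param node A parsed `bel_term` or `bel_statement`.
#' @param vocab A `bel_dictionary` serving as namespace catalog.
#' @param config A [bel_validate_config()].
#' @return A data.frame of diagnostics with columns `severity`, `code`,
#'   `message`, `start`, `end`; zero rows means the node is valid.
#' @examples
#' vocab <- fixture_dictionaries()
#' s <- parse_bel_statement('a(CHEBI:"N-acetyl-D-galactosamine") -| p(HGNC:FUS)')
#' bel_validate(s, vocab)  # no diagnostics
#' @export
bel_validate <- function(node, vocab, config = bel_validate_config()) {
  if (inherits(node, "bel_statement")) {
    rbind(.validate_term(node$subject, vocab, config),
          if (inherits(node$object, "bel_statement"))
            bel_validate(node$object, vocab, config)
          else .validate_term(node$object, vocab, config))
  } else if (inherits(node, "bel_term")) {
    .validate_term(node, vocab, config)
  } else {
    stop("node must be a bel_term or bel_statement", call. = FALSE)
  }
}

#' Validate a BEL expression string
#'
#' Like [bel_validate()] but starting from text: a parse failure is reported
#' as a single `SYNTAX` error diagnostic carrying the character offset rather
#' than thrown.
#'
#' @param text A BEL statement (or bare term) string.
#' @inheritParams bel_validate
#' @return A diagnostics data.frame.
#' @export
bel_validate_text <- function(text, vocab, config = bel_validate_config()) {
  node <- tryCatch(
    parse_bel_statement(text),
    bel_syntax_error = function(e) e)
  if (inherits(node, "bel_syntax_error")) {
    term <- tryCatch(parse_bel_term(text), bel_syntax_error = function(e) NULL)
    if (is.null(term))
      return(diag_row("error", "SYNTAX", conditionMessage(node), node$pos))
    node <- term
  }
  bel_validate(node, vocab, config)
}

#' Is a BEL expression valid?
#'
#' @inheritParams bel_validate_text
#' @return `TRUE` when validation produces no error-severity diagnostics
#'   (warnings such as `PLACEHOLDER` do not make a statement invalid).
#' @export
bel_is_valid <- function(text, vocab, config = bel_validate_config()) {
  d <- bel_validate_text(text, vocab, config)
  !any(d$severity == "error")
}

#' Export diagnostics as JSON records
#'
#' @param diagnostics A diagnostics data.frame from [bel_validate()].
#' @return A JSON array string of `{severity, code, message, start, end}`
#'   records.
#' @export
diagnostics_json <- function(diagnostics) {
  jsonlite::toJSON(diagnostics, dataframe = "rows", na = "null",
                   auto_unbox = TRUE)
}
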