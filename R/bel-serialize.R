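# Canonical form and serialization.
#
# Canonical text rules: ASCII predicates with a single surrounding space; no
# spaces inside argument lists; concept values are double-quoted exactly when
# they contain a character outside [A-Za-z0-9]; complex members are sorted
# lexicographically by their canonical text (binding partners are unordered);
# nested object statements are parenthesized.

.quote_value <- function(value) {
  if (grepl("[^A-Za-z0-9]", value)) paste0("\"", value, "\"") else value
}

.format_pmod <- function(m) {
  fields <- c(m$type, m$residue,
              if (is.na(m$position)) NA_character_ else as.character(m$position))
  fields <- fields[!is.na(fields)]
  paste0("pmod(", paste(fields, collapse = ","), ")")
}

.format_term <- function(t) {
  fn <- t$fn
  if (is_entity_term(t)) {
    inner <- paste0(t$ns, ":", .quote_value(t$value))
    if (length(t$pmods))
      inner <- paste(c(inner, vapply(t$pmods, .format_pmod, character(1))),
                     collapse = ",")
    return(paste0(fn, "(", inner, ")"))
  }
  if (fn == "tloc") {
    inner <- .format_term(t$args[[1L]])
    if (!is.null(t$loc))
      inner <- paste0(inner, ",", t$loc$ns, ":", .quote_value(t$loc$value))
    return(paste0("tloc(", inner, ")"))
  }
  if (fn == "complex") {
    return(paste0("complex(",
                  paste(vapply(t$args, .format_term, character(1)),
                        collapse = ","), ")"))
  }
  paste0(fn, "(", .format_term(t$args[[1L]]), ")")
}

#' Canonicalize a BEL term or statement
#'
#' Produces the deterministic normal form used throughout the package for
#' equality and scoring: complex members sorted by canonical text, glyphs and
#' quoting normalized (quoting is a property of serialization, so a parsed
#' node is already quote-normalized). Canonicalization is idempotent.
#'
#' @param x A `bel_term` or `bel_statement`.
#' @return An object of the same class.
#' @export
bel_canonical <- function(x) {
  UseMethod("bel_canonical")
}

#' @export
bel_canonical.bel_term <- function(x) {
  if (length(x$args))
    x$args <- lapply(x$args, bel_canonical)
  if (x$fn == "complex" && length(x$args) > 1L) {
    ser <- vapply(x$args, .format_term, character(1))
    x$args <- x$args[order(ser, method = "radix")]
  }
  x
}

#' @export
bel_canonical.bel_statement <- function(x) {
  x$subject <- bel_canonical(x$subject)
  x$object <- bel_canonical(x$object)
  x
}

#' Serialize a BEL term or statement
#'
#' @param x A `bel_term` or `bel_statement`.
#' @param dialect `"symbolic"` emits `->`/`-|`/`--` (canonical form);
#'   `"keyword"` emits `increases`/`decreases`/`association` as used in
#'   BELScript documents.
#' @return A single string. `parse_bel_statement(bel_serialize(s))` is
#'   structurally identical to `s` (round-trip law).
#' @export
bel_serialize <- function(x, dialect = c("symbolic", "keyword")) {
  dialect <- match.arg(dialect)
  if (inherits(x, "bel_term")) return(.format_term(x))
  stopifnot(inherits(x, "bel_statement"))
  pred <- x$relation
  if (dialect == "keyword")
    pred <- names(BEL_PREDICATE_KEYWORDS)[match(pred, BEL_PREDICATE_KEYWORDS)]
  obj <- if (inherits(x$object, "bel_statement"))
    paste0("(", bel_serialize(x$object, dialect), ")")
  else .format_term(x$object)
  paste(.format_term(x$subject), pred, obj)
}

#' Canonical text of a BEL node
#'
#' Shorthand for `bel_serialize(bel_canonical(x))`; two nodes are considered
#' equal exactly when their canonical texts agree.
#'
#' @inheritParams bel_serialize
#' @return A single string.
#' @export
bel_text <- function(x, dialect = "symbolic") {
  bel_serialize(bel_canonical(x), dialect = dialect)
}

#' Canonicalize a BEL expression string
#'
#' Parses `text` (statement first, then bare term) and returns its canonical
#' text.
#'
#' @param text A BEL statement or term string.
#' @return The canonical serialization.
#' @export
bel_canonical_text <- function(text) {
  node <- tryCatch(parse_bel_statement(text), bel_syntax_error = function(e) NULL)
  if (is.null(node)) node <- parse_bel_term(text)
  bel_text(node)
}
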