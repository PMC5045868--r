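# BEL expression data model.
#
# A BEL term is one of:
#   * an entity term  -- a(), p(), r(), bp(), or a named complex(NS:value);
#     carries one namespace:value and, for p()/r(), optional pmod() records
#   * a wrapper term  -- deg(), sec(), surf(), act(); wraps exactly one term
#   * a translocation -- tloc(term [, GOCC:location])
#   * a composed complex(term, term, ...) with >= 1 member
# A BEL statement is subject/predicate/object where the object may itself be
# a parenthesized statement (nesting is only permitted on the object side).

BEL_ENTITY_FUNCTIONS  <- c("a", "p", "r", "bp")
BEL_WRAPPER_FUNCTIONS <- c("deg", "sec", "surf", "act")
BEL_FUNCTIONS <- c(BEL_ENTITY_FUNCTIONS, BEL_WRAPPER_FUNCTIONS,
                   "tloc", "complex")

#' BEL predicates in canonical (symbolic) form
#' @export
BEL_PREDICATES <- c("->", "-|", "--")
BEL_PREDICATE_KEYWORDS <- c(increases = "->", decreases = "-|",
                            association = "--")

#' Construct a BEL term
#'
#' Low-level constructor used by the parser and the BEL writer. Most users
#' will obtain terms from [parse_bel_term()] instead.
#'
#' @param fn Function symbol, one of `a`, `p`, `r`, `bp`, `deg`, `sec`,
#'   `surf`, `act`, `tloc`, `complex`.
#' @param ns,value Namespace symbol and concept name for entity-bearing terms
#'   (including named complexes such as `complex(SCOMP:"AP-1 Complex")`).
#' @param pmods List of protein-modification records created with
#'   [bel_pmod()]; only meaningful for `p()`/`r()` terms.
#' @param args List of wrapped member terms for `deg`/`sec`/`surf`/`act`
#'   (one term), `tloc` (one term) and `complex` (one or more terms).
#' @param loc For `tloc`, the target location as `list(ns =, value =)`, or
#'   `NULL` when the location is unknown.
#' @return An object of class `bel_term`.
#' @export
bel_term <- function(fn, ns = NA_character_, value = NA_character_,
                     pmods = list(), args = list(), loc = NULL) {
  if (!fn %in% BEL_FUNCTIONS)
    stop("unknown BEL function '", fn, "'", call. = FALSE)
  if (fn %in% BEL_ENTITY_FUNCTIONS && (is.na(ns) || is.na(value)))
    stop(fn, "() requires a namespace:value", call. = FALSE)
  if (fn %in% BEL_WRAPPER_FUNCTIONS && length(args) != 1L)
    stop(fn, "() wraps exactly one term", call. = FALSE)
  if (fn == "tloc" && length(args) != 1L)
    stop("tloc() wraps exactly one term", call. = FALSE)
  if (fn == "complex" && length(args) == 0L && (is.na(ns) || is.na(value)))
    stop("complex requires at least one entity", call. = FALSE)
  if (length(pmods) && !fn %in% c("p", "r"))
    stop("pmod outside protein/RNA term", call. = FALSE)
  structure(list(fn = fn, ns = ns, value = value,
                 pmods = pmods, args = args, loc = loc),
            class = "bel_term")
}

#' Construct a protein-modification record
#'
#' @param type Modification type code (e.g. `"P"` for phosphorylation); may
#'   be `NA` for a bare `pmod()`.
#' @param residue One-letter amino-acid code of the modified residue, or `NA`.
#' @param position Integer sequence position, or `NA`.
#' @return A list of class `bel_pmod`.
#' @export
bel_pmod <- function(type = NA_character_, residue = NA_character_,
                     position = NA_integer_) {
  if (!is.na(position)) position <- as.integer(position)
  structure(list(type = type, residue = residue, position = position),
            class = "bel_pmod")
}

#' Construct a BEL statement
#'
#' @param subject A `bel_term` (statements are never nested on the subject
#'   side).
#' @param relation Predicate: `"->"` (increases), `"-|"` (decreases) or
#'   `"--"` (association). Keyword spellings are accepted and normalized.
#' @param object A `bel_term`, or a `bel_statement` for a nested object.
#' @param evidence Optional free-text provenance (usually the evidence
#'   sentence).
#' @return An object of class `bel_statement`.
#' @export
bel_statement <- function(subject, relation, object, evidence = NULL) {
  if (relation %in% names(BEL_PREDICATE_KEYWORDS))
    relation <- BEL_PREDICATE_KEYWORDS[[relation]]
  if (!relation %in% BEL_PREDICATES)
    stop("unknown predicate '", relation, "'", call. = FALSE)
  if (!inherits(subject, "bel_term"))
    stop("statement subject must be a BEL term", call. = FALSE)
  if (!inherits(object, c("bel_term", "bel_statement")))
    stop("statement object must be a BEL term or statement", call. = FALSE)
  structure(list(subject = subject, relation = relation, object = object,
                 evidence = evidence),
            class = "bel_statement")
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", bel_text(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", bel_text(x), "\n", sep = "")
  if (!is.null(x$evidence))
    cat("  evidence: ", x$evidence, "\n", sep = "")
  invisible(x)
}

is_entity_term <- function(t) {
  t$fn %in% BEL_ENTITY_FUNCTIONS || (t$fn == "complex" && !is.na(t$ns))
}

is_placeholder_term <- function(t) {
  inherits(t, "bel_term") && !is.na(t$ns) && t$ns == "PH"
}

#' Head entity of a term or statement
#'
#' The head entity of an entity term is its own `namespace:value`; wrappers,
#' translocations and composed complexes delegate to their first (canonical)
#' member; for a nested statement the head is the head of its object. Used by
#' the relationship-level scorer.
#'
#' @param x A `bel_term` or `bel_statement`.
#' @return A single string `"NS:value"`.
#' @export
bel_head_entity <- function(x) {
  if (inherits(x, "bel_statement")) return(bel_head_entity(x$object))
  if (is_entity_term(x)) return(paste0(x$ns, ":", x$value))
  args <- x$args
  if (x$fn == "complex" && length(args) > 1L) {
    ser <- vapply(args, function(a) bel_text(a), character(1))
    args <- args[order(ser)]
  }
  bel_head_entity(args[[1L]])
}
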