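# Recursive-descent parser for the BEL statement subset used in
# sentence-level curation. Character offsets are 1-based and refer to the
# glyph-normalized input; they are carried on syntax errors and on parsed
# nodes (attribute "pos") so the validator can point at the offending spot.

#' Normalize typographic glyphs to ASCII
#'
#' Literature-derived text uses en-dashes, true minus signs and curly quotes;
#' these are mapped onto the ASCII characters the grammar expects before
#' lexing.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
bel_normalize_glyphs <- function(text) {
  text <- gsub("[\u2212\u2013\u2014]", "-", text)
  text <- gsub("[\u201c\u201d]", "\"", text)
  gsub("[\u2018\u2019]", "'", text)
}

bel_syntax_error <- function(message, pos) {
  stop(errorCondition(sprintf("%s at position %d", message, pos),
                      pos = pos,
                      class = c("bel_syntax_error", "error", "condition")))
}

.new_cursor <- function(text) {
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$n <- length(env$chars)
  env$pos <- 1L
  env
}

.at_end <- function(cur) cur$pos > cur$n
.peek <- function(cur) if (.at_end(cur)) "" else cur$chars[cur$pos]
.advance <- function(cur) cur$pos <- cur$pos + 1L

.skip_ws <- function(cur) {
  while (!.at_end(cur) && grepl("[ \t\r\n]", cur$chars[cur$pos]))
    .advance(cur)
}

.read_while <- function(cur, pattern) {
  start <- cur$pos
  while (!.at_end(cur) && grepl(pattern, cur$chars[cur$pos]))
    .advance(cur)
  if (cur$pos == start) return("")
  paste(cur$chars[start:(cur$pos - 1L)], collapse = "")
}

.read_ident <- function(cur) .read_while(cur, "[A-Za-z0-9_]")

# A concept value: double-quoted string (quotes stripped) or a bare token.
.read_value <- function(cur) {
  if (.peek(cur) == "\"") {
    open <- cur$pos
    .advance(cur)
    start <- cur$pos
    while (!.at_end(cur) && .peek(cur) != "\"") .advance(cur)
    if (.at_end(cur)) bel_syntax_error("unterminated quoted value", open)
    value <- if (cur$pos > start)
      paste(cur$chars[start:(cur$pos - 1L)], collapse = "") else ""
    .advance(cur)
    return(value)
  }
  value <- .read_while(cur, "[A-Za-z0-9_.+'-]")
  if (!nzchar(value)) bel_syntax_error("expected concept value", cur$pos)
  value
}

.expect_close <- function(cur, open_pos) {
  .skip_ws(cur)
  if (.peek(cur) != ")")
    bel_syntax_error("unbalanced parentheses (missing ')')", open_pos)
  .advance(cur)
}

# ---- predicates -------------------------------------------------------------

.p_predicate <- function(cur) {
  if (.at_end(cur)) bel_syntax_error("missing predicate", cur$pos)
  two <- paste0(.peek(cur),
                if (cur$pos + 1L <= cur$n) cur$chars[cur$pos + 1L] else "")
  if (two %in% BEL_PREDICATES) {
    cur$pos <- cur$pos + 2L
    return(two)
  }
  start <- cur$pos
  word <- .read_ident(cur)
  if (nzchar(word) && word %in% names(BEL_PREDICATE_KEYWORDS))
    return(BEL_PREDICATE_KEYWORDS[[word]])
  bel_syntax_error("missing predicate", start)
}

# ---- terms ------------------------------------------------------------------

# Parses one argument-position element: a full term, a bare NS:value concept
# (list marker) or a pmod() record.
.p_element <- function(cur) {
  .skip_ws(cur)
  start <- cur$pos
  name <- .read_ident(cur)
  if (!nzchar(name)) bel_syntax_error("expected a term", cur$pos)
  .skip_ws(cur)
  ch <- .peek(cur)
  if (ch == ":") {
    .advance(cur)
    .skip_ws(cur)
    value <- .read_value(cur)
    return(list(kind = "concept", ns = name, value = value, pos = start))
  }
  if (ch != "(")
    bel_syntax_error("expected '(' or ':' after identifier", cur$pos)
  open_pos <- cur$pos
  .advance(cur)
  if (name == "pmod") return(.p_pmod_args(cur, start, open_pos))
  if (!name %in% BEL_FUNCTIONS)
    bel_syntax_error(sprintf("unknown function '%s'", name), start)
  args <- list()
  .skip_ws(cur)
  if (.peek(cur) != ")") {
    repeat {
      args[[length(args) + 1L]] <- .p_element(cur)
      .skip_ws(cur)
      if (.peek(cur) == ",") {
        .advance(cur)
        .skip_ws(cur)
        if (.peek(cur) == ")")
          bel_syntax_error("dangling comma in argument list", cur$pos)
        next
      }
      break
    }
  }
  .expect_close(cur, open_pos)
  .assemble_term(name, args, start)
}

.p_pmod_args <- function(cur, start, open_pos) {
  fields <- character(0)
  .skip_ws(cur)
  if (.peek(cur) != ")") {
    repeat {
      tok <- .read_while(cur, "[A-Za-z0-9]")
      if (!nzchar(tok))
        bel_syntax_error("expected pmod argument", cur$pos)
      fields <- c(fields, tok)
      .skip_ws(cur)
      if (.peek(cur) == ",") {
        .advance(cur)
        .skip_ws(cur)
        next
      }
      break
    }
  }
  .expect_close(cur, open_pos)
  if (length(fields) > 3L)
    bel_syntax_error("pmod takes at most (type, residue, position)", start)
  pos <- NA_integer_
  if (length(fields) == 3L) {
    if (!grepl("^[0-9]+$", fields[3L]))
      bel_syntax_error("pmod position must be an integer", start)
    pos <- as.integer(fields[3L])
  }
  m <- bel_pmod(type = if (length(fields) >= 1L) fields[1L] else NA_character_,
                residue = if (length(fields) >= 2L) fields[2L] else NA_character_,
                position = pos)
  list(kind = "pmod", pmod = m, pos = start)
}

.require_term <- function(el, what) {
  if (inherits(el, "bel_term")) return(el)
  if (identical(el$kind, "pmod"))
    bel_syntax_error("pmod outside protein/RNA term", el$pos)
  bel_syntax_error(paste0(what, " must be a BEL term"), el$pos)
}

.assemble_term <- function(fn, args, start) {
  out <- NULL
  if (fn %in% BEL_ENTITY_FUNCTIONS) {
    if (length(args) == 0L || !identical(args[[1L]]$kind, "concept"))
      bel_syntax_error(sprintf("%s() requires a namespace:value", fn), start)
    pmods <- list()
    if (length(args) > 1L) {
      for (extra in args[-1L]) {
        if (!identical(extra$kind, "pmod"))
          bel_syntax_error(sprintf("unexpected argument in %s()", fn),
                           extra$pos)
        if (!fn %in% c("p", "r"))
          bel_syntax_error("pmod outside protein/RNA term", extra$pos)
        pmods[[length(pmods) + 1L]] <- extra$pmod
      }
    }
    out <- bel_term(fn, ns = args[[1L]]$ns, value = args[[1L]]$value,
                    pmods = pmods)
  } else if (fn %in% BEL_WRAPPER_FUNCTIONS) {
    if (length(args) != 1L)
      bel_syntax_error(sprintf("%s() wraps exactly one term", fn), start)
    out <- bel_term(fn, args = list(.require_term(args[[1L]],
                                                  paste0(fn, "() argument"))))
  } else if (fn == "tloc") {
    if (length(args) < 1L || length(args) > 2L)
      bel_syntax_error("tloc() takes a term and an optional location", start)
    inner <- .require_term(args[[1L]], "tloc() argument")
    loc <- NULL
    if (length(args) == 2L) {
      if (!identical(args[[2L]]$kind, "concept"))
        bel_syntax_error("tloc() location must be a namespace:value",
                         args[[2L]]$pos)
      loc <- list(ns = args[[2L]]$ns, value = args[[2L]]$value)
    }
    out <- bel_term("tloc", args = list(inner), loc = loc)
  } else if (fn == "complex") {
    if (length(args) == 0L)
      bel_syntax_error("complex requires at least one entity", start)
    if (length(args) == 1L && identical(args[[1L]]$kind, "concept")) {
      out <- bel_term("complex", ns = args[[1L]]$ns, value = args[[1L]]$value)
    } else {
      members <- lapply(args, .require_term, what = "complex member")
      out <- bel_term("complex", args = members)
    }
  } else {
    bel_syntax_error(sprintf("unknown function '%s'", fn), start)
  }
  attr(out, "pos") <- start
  out
}

.p_term <- function(cur) {
  el <- .p_element(cur)
  if (inherits(el, "bel_term")) return(el)
  if (identical(el$kind, "concept"))
    bel_syntax_error("bare namespace:value needs an abundance function",
                     el$pos)
  bel_syntax_error("pmod outside protein/RNA term", el$pos)
}

.p_statement <- function(cur) {
  subject <- .p_term(cur)
  .skip_ws(cur)
  relation <- .p_predicate(cur)
  .skip_ws(cur)
  if (.at_end(cur)) bel_syntax_error("missing object", cur$pos)
  if (.peek(cur) == "(") {
    open_pos <- cur$pos
    .advance(cur)
    object <- .p_statement(cur)
    .expect_close(cur, open_pos)
  } else {
    object <- .p_term(cur)
  }
  bel_statement(subject, relation, object)
}

.finish <- function(cur, node) {
  force(node)  # parse before inspecting the cursor (lazy evaluation)
  .skip_ws(cur)
  if (!.at_end(cur))
    bel_syntax_error("unexpected trailing input", cur$pos)
  node
}

#' Parse a BEL statement
#'
#' Accepts symbolic (`->`, `-|`, `--`) and keyword (`increases`, `decreases`,
#' `association`) predicate spellings; en-dash/minus and curly-quote glyph
#' variants are normalized before lexing. Parenthesized statements are
#' accepted as objects (nesting on the object side only).
#'
#' @param text A single BEL expression string.
#' @return A `bel_statement`.
#' @seealso [parse_bel_term()] for inputs that are a bare term.
#' @examples
#' parse_bel_statement('a(CHEBI:corticosteroid) -| bp(MESHPP:"Oxidative Stress")')
#' @export
parse_bel_statement <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  cur <- .new_cursor(bel_normalize_glyphs(text))
  .finish(cur, .p_statement(cur))
}

#' Parse a BEL term
#'
#' @param text A single BEL term string such as
#'   `p(HGNC:SREBF1, pmod(P,T,426))`.
#' @return A `bel_term`.
#' @export
parse_bel_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  cur <- .new_cursor(bel_normalize_glyphs(text))
  .finish(cur, .p_term(cur))
}
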