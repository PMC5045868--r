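# Curation document model, pipeline orchestration, BELScript export/import
# and validity bookkeeping.
#
# A curation document carries the raw text, its sentences, citation
# information, and the proposed statements with their evidence sentences,
# export flags and context annotations. Export to BELScript is gated: one
# invalid or placeholder-carrying flagged statement, or missing citation
# information, refuses the export of the whole document.

.NAMESPACE_URLS <- c(
  HGNC = "http://resource.belframework.org/belframework/1.0/namespace/hgnc-approved-symbols.belns",
  MGI = "http://resource.belframework.org/belframework/1.0/namespace/mgi-approved-symbols.belns",
  RGD = "http://resource.belframework.org/belframework/1.0/namespace/rgd-approved-symbols.belns",
  SFAM = "http://resource.belframework.org/belframework/1.0/namespace/selventa-protein-families.belns",
  SCOMP = "http://resource.belframework.org/belframework/1.0/namespace/selventa-named-complexes.belns",
  GOCC = "http://resource.belframework.org/belframework/1.0/namespace/go-cellular-component-terms.belns",
  GOBP = "http://resource.belframework.org/belframework/1.0/namespace/go-biological-processes-names.belns",
  SCHEM = "http://resource.belframework.org/belframework/1.0/namespace/selventa-legacy-chemical-names.belns",
  CHEBI = "http://resource.belframework.org/belframework/1.0/namespace/chebi-names.belns",
  CHEMBL = "urn:namespace:chembl",
  MESHD = "http://resource.belframework.org/belframework/1.0/namespace/mesh-diseases.belns",
  MESHPP = "http://resource.belframework.org/belframework/1.0/namespace/mesh-biological-processes.belns",
  PH = "urn:namespace:placeholder")

.ANNOTATION_URLS <- c(
  MESHAnatomy = "http://resource.belframework.org/belframework/1.0/annotation/mesh-anatomy.belanno",
  CellLine = "http://resource.belframework.org/belframework/1.0/annotation/atcc-cell-line.belanno",
  CellStructure = "http://resource.belframework.org/belframework/1.0/annotation/mesh-cell-structure.belanno")

.empty_statement_table <- function() {
  df <- data.frame(statement = character(0), evidence = character(0),
                   export = logical(0), origin = character(0),
                   stringsAsFactors = FALSE)
  df$annotations <- list()
  df
}

#' Construct a curation document
#'
#' @param id Document identifier.
#' @param text Document text.
#' @param citation List with fields `source`, `title`, `journal`, `authors`,
#'   `date`, `pmid` (all optional until export; `source` defaults to
#'   `"PubMed"`).
#' @param statements Statement table (`statement`, `evidence`, `export`,
#'   `origin`, list-column `annotations`).
#' @param status One of `queued`, `processing`, `processed`, `failed`.
#' @return An object of class `curation_document`.
#' @export
curation_document <- function(id, text = "", citation = list(),
                              statements = .empty_statement_table(),
                              status = "queued") {
  stopifnot(status %in% c("queued", "processing", "processed", "failed"))
  citation <- utils::modifyList(list(source = "PubMed", title = NULL,
                                     journal = NULL, authors = NULL,
                                     date = NULL, pmid = NULL), citation)
  structure(list(id = id, text = text, sentences = split_sentences(text),
                 citation = citation, statements = statements,
                 status = status, failure = NULL),
            class = "curation_document")
}

#' @export
print.curation_document <- function(x, ...) {
  cat("<curation_document> ", x$id, " [", x$status, "]: ",
      nrow(x$statements), " statements (", sum(x$statements$export),
      " flagged for export)\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param associations Run the co-occurrence association baseline alongside
#'   event extraction.
#' @param lexicon Trigger lexicon for [extract_events()].
#' @param harmonize A [harmonize_config()].
#' @param assoc An [association_config()].
#' @param ruleset A [bel_ruleset()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(associations = TRUE,
                            lexicon = trigger_lexicon(),
                            harmonize = harmonize_config(),
                            assoc = association_config(),
                            ruleset = bel_ruleset()) {
  structure(list(associations = associations, lexicon = lexicon,
                 harmonize = harmonize, assoc = assoc, ruleset = ruleset),
            class = "pipeline_config")
}

#' Run the extraction pipeline on one document
#'
#' Sentence splitting, dictionary tagging, harmonization, context mapping,
#' event and association extraction and BEL translation. Pre-computed
#' standoff events (e.g. from an external event extraction system) can be
#' supplied to replace the baseline event extractor. A stage failure marks
#' the document `failed` rather than raising.
#'
#' @param text Document text.
#' @param dict A `bel_dictionary`.
#' @param config A [pipeline_config()].
#' @param id Document id.
#' @param standoff Optional list from [read_standoff()] whose events are
#'   used instead of running [extract_events()].
#' @return A `curation_document` with status `processed` (or `failed`),
#'   proposed statements and document-scope context annotations attached to
#'   every statement.
#' @export
run_pipeline <- function(text, dict, config = pipeline_config(),
                         id = "doc1", standoff = NULL) {
  doc <- curation_document(id, text, status = "processing")
  result <- tryCatch({
    mentions <- annotate_mentions(text, dict, doc_id = id)
    mentions <- harmonize_mentions(mentions, text, config$harmonize)
    context <- map_context(mentions)
    annotations <- if (nrow(context))
      lapply(seq_len(nrow(context)), function(i)
        list(class = context$class[i], value = context$value[i]))
    else list()
    rows <- list()
    sentences <- doc$sentences
    if (!is.null(standoff)) {
      resolved <- resolve_events(standoff$events, .standoff_selected(
        standoff$mentions, dict, text, config$harmonize))
      proposed <- translate_sentence(resolved, NULL, text, config$ruleset)
      if (nrow(proposed)) rows[[length(rows) + 1L]] <- proposed
    }
    for (i in seq_len(nrow(sentences))) {
      sent <- sentences[i, , drop = FALSE]
      sm <- sentence_mentions(mentions, sent)
      resolved <- list()
      if (is.null(standoff)) {
        events <- extract_events(sent$text, sm, config$lexicon)
        resolved <- resolve_events(events, sm)
      }
      pairs <- if (config$associations)
        extract_associations(sent$text, sm, config$assoc)
      else NULL
      proposed <- translate_sentence(resolved, pairs, sent$text,
                                     config$ruleset, mentions = sm)
      if (nrow(proposed)) rows[[length(rows) + 1L]] <- proposed
    }
    statements <- do.call(rbind, c(list(data.frame(
      statement = character(0), evidence = character(0),
      origin = character(0), stringsAsFactors = FALSE)), rows))
    statements <- statements[!duplicated(statements$statement), ,
                             drop = FALSE]
    rownames(statements) <- NULL
    statements$export <- rep(FALSE, nrow(statements))
    statements$annotations <- rep(list(annotations), nrow(statements))
    statements[, c("statement", "evidence", "export", "origin",
                   "annotations")]
  }, error = function(e) e)
  if (inherits(result, "error")) {
    doc$status <- "failed"
    doc$failure <- conditionMessage(result)
  } else {
    doc$statements <- result
    doc$status <- "processed"
  }
  doc
}

# Attach selected_* columns to standoff mentions via dictionary lookup.
.standoff_selected <- function(mentions, dict, doc_text, config) {
  mentions$candidates <- lapply(mentions$surface, dict_lookup, dict = dict)
  keep <- vapply(mentions$candidates, nrow, 0L) > 0L
  harmonize_mentions(mentions[keep, , drop = FALSE], doc_text, config)
}

# ---- BELScript --------------------------------------------------------------

.bs_quote <- function(x) paste0("\"", gsub("\"", "'", x), "\"")

belscript_refusal <- function(message, offending) {
  stop(errorCondition(message, offending = offending,
                      class = c("belscript_export_refused", "error",
                                "condition")))
}

#' Write a curation document as BELScript
#'
#' Only statements flagged `export` are written. The export is refused for
#' the whole document when any flagged statement has a validation error or a
#' placeholder warning, or when the citation lacks a PubMed id; the refusal
#' condition (class `belscript_export_refused`) lists the offending
#' statements.
#'
#' @param doc A `curation_document`.
#' @param vocab A `bel_dictionary` for validation.
#' @param config A [bel_validate_config()].
#' @return The BELScript text (single string). A document with zero flagged
#'   statements yields a header-only script with a warning.
#' @export
write_belscript <- function(doc, vocab, config = bel_validate_config()) {
  st <- doc$statements[doc$statements$export, , drop = FALSE]
  offending <- character(0)
  if (is.null(doc$citation$pmid))
    offending <- c(offending, "<citation: missing PubMed id>")
  for (i in seq_len(nrow(st))) {
    d <- bel_validate_text(st$statement[i], vocab, config)
    if (any(d$severity == "error") || any(d$code == "PLACEHOLDER"))
      offending <- c(offending, st$statement[i])
  }
  if (length(offending) && nrow(st) > 0L)
    belscript_refusal(
      paste0("export refused for document ", doc$id, "; offending: ",
             paste(offending, collapse = "; ")),
      offending)
  header_source <- if (nrow(st)) st$statement else doc$statements$statement
  used_ns <- sort(unique(unlist(lapply(header_source, function(s)
    .statement_namespaces(s)))))
  used_anno <- sort(unique(unlist(lapply(st$annotations, function(a)
    vapply(a, `[[`, "", "class")))))
  lines <- character(0)
  for (ns in used_ns) {
    url <- .NAMESPACE_URLS[[ns]] %||% paste0("urn:namespace:", tolower(ns))
    lines <- c(lines, sprintf("DEFINE NAMESPACE %s AS URL %s", ns,
                              .bs_quote(url)))
  }
  for (an in used_anno) {
    url <- .ANNOTATION_URLS[[an]] %||% paste0("urn:annotation:", tolower(an))
    lines <- c(lines, sprintf("DEFINE ANNOTATION %s AS URL %s", an,
                              .bs_quote(url)))
  }
  lines <- c(lines, "")
  if (nrow(st) == 0L) {
    warning("document ", doc$id, " has no statements flagged for export; ",
            "writing a header-only BELScript")
    return(paste(lines, collapse = "\n"))
  }
  cite <- sprintf("SET Citation = {%s,%s,%s}",
                  .bs_quote(doc$citation$source %||% "PubMed"),
                  .bs_quote(doc$citation$journal %||% ""),
                  .bs_quote(doc$citation$pmid))
  for (i in seq_len(nrow(st))) {
    block <- c(cite,
               sprintf("SET Evidence = %s", .bs_quote(st$evidence[i])))
    annos <- st$annotations[[i]]
    for (a in annos)
      block <- c(block, sprintf("SET %s = %s", a$class, .bs_quote(a$value)))
    stmt <- bel_serialize(bel_canonical(parse_bel_statement(st$statement[i])),
                          dialect = "keyword")
    block <- c(block, stmt)
    for (a in rev(annos)) block <- c(block, sprintf("UNSET %s", a$class))
    block <- c(block, "UNSET Evidence", "")
    lines <- c(lines, block)
  }
  paste(lines, collapse = "\n")
}

.statement_namespaces <- function(text) {
  node <- tryCatch(parse_bel_statement(text), bel_syntax_error = function(e)
    tryCatch(parse_bel_term(text), bel_syntax_error = function(e2) NULL))
  if (is.null(node)) return(character(0))
  terms <- if (inherits(node, "bel_statement")) .statement_terms(node)
  else list(node)
  ns <- unlist(lapply(terms, function(t) {
    collect <- function(t) {
      out <- if (!is.na(t$ns)) t$ns else character(0)
      if (!is.null(t$loc)) out <- c(out, t$loc$ns)
      c(out, unlist(lapply(t$args, collect), use.names = FALSE))
    }
    collect(t)
  }), use.names = FALSE)
  unique(ns)
}

#' Read a BELScript document
#'
#' Accepts the dialect written by [write_belscript()] and is tolerant of
#' unknown `SET` keys, which are kept as opaque context annotations.
#' Statement lines that fail to parse are retained with a diagnostic rather
#' than dropped.
#'
#' @param text BELScript text (single string or lines).
#' @param id Document id for the resulting object.
#' @return A `curation_document`; parsed statements carry their evidence,
#'   annotations and `export = TRUE`. Column `diagnostic` holds the parse
#'   error message for invalid statement lines (`NA` otherwise).
#' @export
read_belscript <- function(text, id = "imported") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
  else text
  citation <- list()
  evidence <- NA_character_
  annos <- list()
  rows <- list()
  unquote <- function(x) sub("^\"(.*)\"$", "\\1", trimws(x))
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "DEFINE ")) next
    if (startsWith(line, "UNSET ")) {
      key <- trimws(sub("^UNSET ", "", line))
      if (key == "Evidence") evidence <- NA_character_
      else annos[[key]] <- NULL
      next
    }
    if (startsWith(line, "SET ")) {
      kv <- regmatches(line, regexec("^SET +([A-Za-z]+) *= *(.*)$", line))[[1L]]
      if (length(kv) == 3L) {
        key <- kv[2L]
        val <- kv[3L]
        if (key == "Citation") {
          parts <- strsplit(gsub("[{}]", "", val), ",")[[1L]]
          parts <- vapply(parts, unquote, "", USE.NAMES = FALSE)
          citation <- list(source = parts[1L] %||% "PubMed",
                           journal = if (length(parts) > 1L) parts[2L],
                           pmid = if (length(parts) > 2L) parts[3L])
        } else if (key == "Evidence") {
          evidence <- unquote(val)
        } else {
          annos[[key]] <- unquote(val)
        }
      }
      next
    }
    # anything else is a statement line
    parsed <- tryCatch(parse_bel_statement(line),
                       bel_syntax_error = function(e) e)
    ok <- !inherits(parsed, "bel_syntax_error")
    rows[[length(rows) + 1L]] <- list(
      statement = if (ok) bel_text(parsed) else line,
      evidence = evidence,
      diagnostic = if (ok) NA_character_ else conditionMessage(parsed),
      annotations = lapply(names(annos), function(k)
        list(class = k, value = annos[[k]])))
  }
  st <- data.frame(
    statement = vapply(rows, `[[`, "", "statement"),
    evidence = vapply(rows, `[[`, "", "evidence"),
    export = rep(TRUE, length(rows)),
    origin = rep("manual", length(rows)),
    diagnostic = vapply(rows, `[[`, "", "diagnostic"),
    stringsAsFactors = FALSE)
  st$annotations <- lapply(rows, `[[`, "annotations")
  doc <- curation_document(id, text = "", citation = citation,
                           status = "processed")
  doc$statements <- st
  doc
}

# ---- validity statistics ----------------------------------------------------

#' Validity statistics over curated documents
#'
#' A statement is invalid when validation yields at least one error
#' (syntax or semantic); a document is invalid when it contains at least one
#' invalid statement. Rates are percentages, reported to 2 decimals for
#' statements and 1 decimal for documents, and 0 when the total is 0.
#'
#' @param x A `synthetic_corpus`, a list of `curation_document`s, or a
#'   character vector of BELScript file paths.
#' @param vocab A `bel_dictionary` for validation.
#' @param config A [bel_validate_config()].
#' @return A list of class `validity_stats`.
#' @export
curation_stats <- function(x, vocab = fixture_dictionaries(),
                           config = bel_validate_config()) {
  docs <- if (inherits(x, "synthetic_corpus")) {
    split(x$statements$statement, x$statements$doc_id)
  } else if (is.character(x)) {
    stmts <- lapply(x, function(path)
      read_belscript(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                           collapse = "\n"))$statements$statement)
    stats::setNames(stmts, x)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE,
                                      "curation_document"))) {
    stats::setNames(lapply(x, function(d) d$statements$statement),
                    vapply(x, `[[`, "", "id"))
  } else {
    stop("unsupported input to curation_stats()", call. = FALSE)
  }
  doc_invalid <- vapply(docs, function(stmts) {
    if (length(stmts) == 0L) return(c(n = 0L, bad = 0L))
    bad <- sum(!vapply(stmts, bel_is_valid, TRUE, vocab = vocab,
                       config = config))
    c(n = length(stmts), bad = bad)
  }, integer(2))
  n_statements <- sum(doc_invalid["n", ])
  n_invalid <- sum(doc_invalid["bad", ])
  n_docs <- length(docs)
  n_bad_docs <- sum(doc_invalid["bad", ] > 0L)
  structure(list(
    n_documents = n_docs,
    n_valid_documents = n_docs - n_bad_docs,
    n_invalid_documents = n_bad_docs,
    n_statements = n_statements,
    n_valid_statements = n_statements - n_invalid,
    n_invalid_statements = n_invalid,
    invalid_statement_rate = if (n_statements == 0L) 0
    else round(100 * n_invalid / n_statements, 2),
    invalid_document_rate = if (n_docs == 0L) 0
    else round(100 * n_bad_docs / n_docs, 1)),
    class = "validity_stats")
}

#' @export
print.validity_stats <- function(x, ...) {
  cat("Documents:  ", x$n_valid_documents, " valid / ",
      x$n_invalid_documents, " invalid (", x$invalid_document_rate,
      "%)\n", sep = "")
  cat("Statements: ", x$n_valid_statements, " valid / ",
      x$n_invalid_statements, " invalid (", x$invalid_statement_rate,
      "%)\n", sep = "")
  invisible(x)
}
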