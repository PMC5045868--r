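# Synthetic corpus and statement generation.
#
# The generator emits miniature curation corpora: templated evidence
# sentences built from the fixture entities, per-sentence gold BEL
# statements, gold mention spans, and an optional defect plan that injects
# exactly one named validation defect into each chosen statement. It exists
# to exercise the validator, the scorer and the curation bookkeeping at
# realistic counts; it makes no attempt to emulate the linguistic
# variability of real abstracts.

#' Defect codes the corpus generator can plant
#' @export
DEFECT_CODES <- c("UNKNOWN_NAMESPACE", "UNKNOWN_VALUE", "MISSING_OBJECT",
                  "UNBALANCED_PARENS")

#' Specification for a synthetic corpus
#'
#' @param n_documents Number of documents.
#' @param n_statements Total number of gold statements (distributed as
#'   evenly as possible over documents, one evidence sentence each).
#' @param n_defects Number of statements to corrupt (each with exactly one
#'   defect).
#' @param n_defect_documents Number of documents the defects are confined
#'   to.
#' @param defect_codes Defect types to cycle through; see `DEFECT_CODES`.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_documents, n_statements, n_defects = 0L,
                        n_defect_documents = min(n_defects, n_documents),
                        defect_codes = DEFECT_CODES) {
  stopifnot(n_documents >= 1L, n_statements >= n_documents)
  if (n_defects > n_statements)
    stop("more defects requested than statements", call. = FALSE)
  if (n_defect_documents > n_documents)
    stop("more defect documents than documents", call. = FALSE)
  if (n_defects > 0L && n_defect_documents < 1L)
    stop("defects requested but no defect documents", call. = FALSE)
  if (n_defects < n_defect_documents)
    stop("each defect document needs at least one defect", call. = FALSE)
  bad <- setdiff(defect_codes, DEFECT_CODES)
  if (length(bad))
    stop("unknown defect codes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_documents = as.integer(n_documents),
                 n_statements = as.integer(n_statements),
                 n_defects = as.integer(n_defects),
                 n_defect_documents = as.integer(n_defect_documents),
                 defect_codes = defect_codes),
            class = "corpus_spec")
}

# ---- random statement construction -----------------------------------------

.statement_pool <- function(dict) {
  e <- dict$entries
  list(gene = e[e$entity_class %in% c("gene_protein", "family"), ,
                drop = FALSE],
       chemical = e[e$entity_class == "chemical", , drop = FALSE],
       bioprocess = e[e$entity_class == "bioprocess", , drop = FALSE],
       complex = e[e$entity_class == "complex", , drop = FALSE])
}

.sample_row <- function(df) df[sample.int(nrow(df), 1L), , drop = FALSE]

.random_entity_term <- function(pool, role = c("subject", "object")) {
  role <- match.arg(role)
  kind <- sample(c("gene", "chemical", "bioprocess", "complex"), 1L,
                 prob = if (role == "subject") c(0.6, 0.3, 0, 0.1)
                 else c(0.5, 0.2, 0.2, 0.1))
  row <- .sample_row(.statement_pool_part(pool, kind))
  base <- switch(kind,
                 gene = bel_term(if (row$entity_class == "family") "p" else "p",
                                 ns = row$namespace, value = row$value),
                 chemical = bel_term("a", ns = row$namespace, value = row$value),
                 bioprocess = bel_term("bp", ns = row$namespace,
                                       value = row$value),
                 complex = bel_term("complex", ns = row$namespace,
                                    value = row$value))
  if (kind == "gene") {
    u <- stats::runif(1)
    if (u < 0.10) {
      base$pmods <- list(bel_pmod("P", sample(c("S", "T", "Y"), 1L),
                                  sample(50:600, 1L)))
    } else if (u < 0.18) {
      base <- bel_term(sample(c("deg", "sec", "surf", "act"), 1L),
                       args = list(base))
    } else if (u < 0.24) {
      base <- bel_term("tloc", args = list(base),
                       loc = list(ns = "GOCC", value = "Nucleus"))
    } else if (u < 0.30) {
      partner <- .sample_row(.statement_pool_part(pool, "gene"))
      base <- bel_term("complex",
                       args = list(base, bel_term("p", ns = partner$namespace,
                                                  value = partner$value)))
    }
  }
  base
}

.statement_pool_part <- function(pool, kind) {
  df <- pool[[kind]]
  if (nrow(df) == 0L) pool$gene else df
}

.random_statement_node <- function(pool, allow_nested = TRUE) {
  subject <- .random_entity_term(pool, "subject")
  relation <- sample(BEL_PREDICATES, 1L, prob = c(0.45, 0.35, 0.2))
  object <- if (allow_nested && stats::runif(1) < 0.15)
    .random_statement_node(pool, allow_nested = FALSE)
  else .random_entity_term(pool, "object")
  bel_statement(subject, relation, object)
}

#' Generate random valid BEL statements
#'
#' Draws statements over the fixture (or a supplied) vocabulary: simple and
#' wrapped abundances, phosphorylation modifications, translocations,
#' complexes, and occasionally nested object statements. Every emitted
#' statement is canonical and validates cleanly against the generating
#' dictionary.
#'
#' @param n Number of statements.
#' @param seed Integer seed; generation is fully determined by `(n, seed)`.
#' @param dict Source dictionary (defaults to [fixture_dictionaries()]).
#' @return Character vector of canonical BEL statement texts.
#' @export
generate_statements <- function(n, seed = 1L, dict = fixture_dictionaries()) {
  pool <- .statement_pool(dict)
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i)
      bel_text(.random_statement_node(pool)), character(1))
  })
}

# ---- defect injection -------------------------------------------------------

.inject_defect <- function(text, code) {
  switch(code,
         UNKNOWN_NAMESPACE = sub("\\(([A-Za-z]+):", "(QQX:", text),
         UNKNOWN_VALUE =
           sub("\\(([A-Za-z]+):(\"[^\"]*\"|[A-Za-z0-9_.+'-]+)",
               "(\\1:ZZZUNKNOWNVALUE", text),
         MISSING_OBJECT = trimws(sub("(-(>|\\||-)).*$", "\\1", text)),
         UNBALANCED_PARENS = sub("\\)([^)]*)$", "\\1", text),
         stop("unknown defect code ", code, call. = FALSE))
}

# ---- sentence realization ---------------------------------------------------

.term_surface <- function(t) {
  if (is_entity_term(t)) return(t$value)
  if (t$fn == "complex")
    return(paste(vapply(t$args, .term_surface, character(1)),
                 collapse = " and "))
  .term_surface(t$args[[1L]])
}

.statement_surface <- function(s) {
  verb <- switch(s$relation, "->" = "increases", "-|" = "decreases",
                 "--" = "is associated with")
  obj <- if (inherits(s$object, "bel_statement"))
    paste("the process by which", .statement_surface(s$object))
  else .term_surface(s$object)
  paste(.term_surface(s$subject), verb, obj)
}

.statement_entities <- function(s) {
  terms <- .statement_terms(s)
  unique(unlist(lapply(terms, .term_entities), use.names = FALSE))
}

#' Generate a synthetic curation corpus
#'
#' Statements are distributed as evenly as possible over documents, one
#' templated evidence sentence per statement. Defects are confined to
#' `n_defect_documents` randomly chosen documents (each receiving at least
#' one) and every defective statement violates exactly the named rule.
#' Generation is fully determined by `(spec, seed)`.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed.
#' @param dict Source dictionary for entities and gold statements.
#' @return A list of class `synthetic_corpus` with elements `spec`, `seed`,
#'   `documents` (`doc_id`, `text`), `sentences` (`doc_id`, `sentence_id`,
#'   `start`, `end`, `text`), `statements` (`doc_id`, `sentence_id`,
#'   `statement`, `defect`) and `mentions` (gold entity spans).
#' @export
generate_corpus <- function(spec, seed = 1L, dict = fixture_dictionaries()) {
  stopifnot(inherits(spec, "corpus_spec"))
  pool <- .statement_pool(dict)
  withr::with_seed(as.integer(seed), {
    per_doc <- rep(spec$n_statements %/% spec$n_documents, spec$n_documents)
    extra <- spec$n_statements %% spec$n_documents
    if (extra > 0L) per_doc[seq_len(extra)] <- per_doc[seq_len(extra)] + 1L
    doc_ids <- sprintf("doc%02d", seq_len(spec$n_documents))

    defect_docs <- if (spec$n_defect_documents > 0L)
      sort(sample.int(spec$n_documents, spec$n_defect_documents))
    else integer(0)
    defects_per_doc <- rep(0L, spec$n_documents)
    defects_per_doc[defect_docs] <- 1L
    remaining <- spec$n_defects - length(defect_docs)
    if (sum(per_doc[defect_docs]) < spec$n_defects)
      stop("defect documents cannot hold the requested defects",
           call. = FALSE)
    while (remaining > 0L) {
      open <- defect_docs[defects_per_doc[defect_docs] <
                            per_doc[defect_docs]]
      d <- open[sample.int(length(open), 1L)]
      defects_per_doc[d] <- defects_per_doc[d] + 1L
      remaining <- remaining - 1L
    }

    docs <- list()
    sentences <- list()
    statements <- list()
    mentions <- list()
    defect_cycle <- 0L
    for (d in seq_len(spec$n_documents)) {
      doc_id <- doc_ids[d]
      n_s <- per_doc[d]
      defect_slots <- if (defects_per_doc[d] > 0L)
        sort(sample.int(n_s, defects_per_doc[d])) else integer(0)
      offset <- 0L
      sent_texts <- character(n_s)
      for (k in seq_len(n_s)) {
        node <- .random_statement_node(pool)
        canonical <- bel_text(node)
        defect <- NA_character_
        text_out <- canonical
        if (k %in% defect_slots) {
          defect_cycle <- defect_cycle + 1L
          defect <- spec$defect_codes[
            (defect_cycle - 1L) %% length(spec$defect_codes) + 1L]
          text_out <- .inject_defect(canonical, defect)
        }
        sentence_id <- sprintf("%s_s%02d", doc_id, k)
        sent <- paste0(.statement_surface(node), ".")
        sent_texts[k] <- sent
        sentences[[length(sentences) + 1L]] <-
          data.frame(doc_id = doc_id, sentence_id = sentence_id,
                     start = offset, end = offset + nchar(sent),
                     text = sent, stringsAsFactors = FALSE)
        statements[[length(statements) + 1L]] <-
          data.frame(doc_id = doc_id, sentence_id = sentence_id,
                     statement = text_out, defect = defect,
                     stringsAsFactors = FALSE)
        for (ent in .statement_entities(node)) {
          value <- sub("^[^:]+:", "", ent)
          ns <- sub(":.*$", "", ent)
          at <- regexpr(value, sent, fixed = TRUE)
          if (at > 0L)
            mentions[[length(mentions) + 1L]] <-
              data.frame(doc_id = doc_id, sentence_id = sentence_id,
                         start = offset + as.integer(at) - 1L,
                         end = offset + as.integer(at) - 1L +
                           attr(at, "match.length"),
                         surface = value, namespace = ns, value = value,
                         stringsAsFactors = FALSE)
        }
        offset <- offset + nchar(sent) + 1L   # single joining space
      }
      docs[[d]] <- data.frame(doc_id = doc_id,
                              text = paste(sent_texts, collapse = " "),
                              stringsAsFactors = FALSE)
    }
    structure(list(spec = spec, seed = as.integer(seed),
                   documents = do.call(rbind, docs),
                   sentences = do.call(rbind, sentences),
                   statements = do.call(rbind, statements),
                   mentions = do.call(rbind, mentions)),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$documents), " documents, ",
      nrow(x$statements), " statements (",
      sum(!is.na(x$statements$defect)), " defective), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits one plain-text file per document, gold mentions in BioNLP `.a1`
#' standoff, a gold statement TSV (`sentence_id`, `statement`) and the
#' defect plan TSV.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus$documents))) {
    doc_id <- corpus$documents$doc_id[i]
    writeLines(corpus$documents$text[i],
               file.path(dir, paste0(doc_id, ".txt")), useBytes = TRUE)
    m <- corpus$mentions[corpus$mentions$doc_id == doc_id, , drop = FALSE]
    a1 <- if (nrow(m)) sprintf("T%d\tEntity %d %d\t%s", seq_len(nrow(m)),
                               m$start, m$end, m$surface) else character(0)
    writeLines(a1, file.path(dir, paste0(doc_id, ".a1")), useBytes = TRUE)
  }
  st <- corpus$statements
  writeLines(c("sentence_id\tstatement",
               paste(st$sentence_id, st$statement, sep = "\t")),
             file.path(dir, "gold_statements.tsv"), useBytes = TRUE)
  defects <- st[!is.na(st$defect), c("sentence_id", "defect"), drop = FALSE]
  writeLines(c("sentence_id\tdefect",
               paste(defects$sentence_id, defects$defect, sep = "\t")),
             file.path(dir, "defect_plan.tsv"), useBytes = TRUE)
  invisible(dir)
}
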