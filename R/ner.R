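# Sentence segmentation and dictionary-based entity tagging.
#
# Offsets are 0-based half-open character ranges relative to the document,
# the convention shared with the standoff reader/writer. Mentions are plain
# data.frames with a list-column of candidate concepts so that the curation
# layer can always show every reading; `harmonize_mentions()` adds the
# arbitrated `selected_*` columns required by downstream extraction.

# Common sentence-internal abbreviations after which a period does not end a
# sentence.
.ABBREVIATIONS <- c("e.g", "i.e", "cf", "et al", "etc", "fig", "Fig", "vs",
                    "ca", "approx", "no", "No", "Dr", "Mr", "Ms")

#' Split text into sentences
#'
#' Rule-based segmentation: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter or digit, unless the period closes a
#' single-letter initial or a common abbreviation. Spans are 0-based
#' half-open, cover all non-whitespace text, do not overlap and come in
#' document order.
#'
#' @param text A single document string.
#' @return A data.frame with columns `start`, `end` (0-based half-open) and
#'   `text`.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (!nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer(0)  # index of last char of each sentence (1-based)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      nxt <- i + 1L
      while (nxt <= n && chars[nxt] == " ") nxt <- nxt + 1L
      follows <- nxt <= n && grepl("[A-Z0-9]", chars[nxt]) && nxt > i + 1L
      if (ch == "." && follows) {
        # look back at the word preceding the period
        j <- i - 1L
        while (j >= 1L && grepl("[A-Za-z.]", chars[j])) j <- j - 1L
        word <- paste(chars[(j + 1L):(i - 1L)], collapse = "")
        if (grepl("^[A-Z]$", word) || word %in% .ABBREVIATIONS)
          follows <- FALSE
      }
      if (follows || nxt > n) breaks <- c(breaks, i)
    }
    i <- i + 1L
  }
  if (length(breaks) == 0L || breaks[length(breaks)] < n)
    breaks <- c(breaks, n)
  starts <- c(1L, breaks[-length(breaks)] + 1L)
  spans <- lapply(seq_along(breaks), function(k) {
    s <- starts[k]
    e <- breaks[k]
    while (s <= e && grepl("[ \t\r\n]", chars[s])) s <- s + 1L
    while (e >= s && grepl("[ \t\r\n]", chars[e])) e <- e - 1L
    if (s > e) return(NULL)
    data.frame(start = s - 1L, end = e,
               text = substr(text, s, e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, spans)
  if (is.null(out)) empty else out
}

.document_tokens <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      token = character(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L,
             token = regmatches(text, list(m))[[1L]],
             stringsAsFactors = FALSE)
}

.empty_mentions <- function() {
  out <- data.frame(doc_id = character(0), sentence_index = integer(0),
                    start = integer(0), end = integer(0),
                    surface = character(0), stringsAsFactors = FALSE)
  out$candidates <- list()
  out
}

#' Tag dictionary entities in a document
#'
#' Each namespace is matched independently with leftmost-longest,
#' token-boundary semantics on normalized synonym keys; hits from different
#' namespaces may overlap, and hits with identical spans are merged into one
#' mention carrying all candidate concepts that share the synonym. Adding
#' dictionary entries never removes mentions.
#'
#' @param text Document text (UTF-8).
#' @param dict A `bel_dictionary` (may span many namespaces).
#' @param doc_id Document identifier recorded on each mention.
#' @return A mention data.frame: `doc_id`, `sentence_index`, `start`, `end`
#'   (0-based half-open), `surface` and list-column `candidates` (data.frame
#'   of `namespace`, `value`, `entity_class`, `organism`).
#' @export
annotate_mentions <- function(text, dict, doc_id = "doc1") {
  idx <- dict_index(dict)
  toks <- .document_tokens(text)
  if (nrow(toks) == 0L || nrow(idx) == 0L) return(.empty_mentions())
  sentences <- split_sentences(text)
  max_len <- max(idx$n_tokens)
  hits <- list()
  for (ns in unique(idx$namespace)) {
    sub <- idx[idx$namespace == ns, , drop = FALSE]
    i <- 1L
    while (i <= nrow(toks)) {
      matched_len <- 0L
      matched_rows <- NULL
      for (len in seq(min(max_len, nrow(toks) - i + 1L), 1L)) {
        window <- toks$token[i:(i + len - 1L)]
        raw <- paste(window, collapse = " ")
        hit <- sub$n_tokens == len &
          ((sub$case_sensitive & sub$key == raw) |
             (!sub$case_sensitive & sub$key == tolower(raw)))
        if (any(hit)) {
          matched_len <- len
          matched_rows <- sub[hit, , drop = FALSE]
          break
        }
      }
      if (matched_len > 0L) {
        start <- toks$start[i]
        end <- toks$end[i + matched_len - 1L]
        hits[[length(hits) + 1L]] <-
          list(start = start, end = end,
               candidates = matched_rows[, c("namespace", "value",
                                             "entity_class", "organism"),
                                         drop = FALSE])
        i <- i + matched_len
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(hits) == 0L) return(.empty_mentions())
  key <- vapply(hits, function(h) paste(h$start, h$end), character(1))
  merged <- lapply(unique(key), function(k) {
    grp <- hits[key == k]
    cands <- unique(do.call(rbind, lapply(grp, `[[`, "candidates")))
    rownames(cands) <- NULL
    list(start = grp[[1L]]$start, end = grp[[1L]]$end, candidates = cands)
  })
  starts <- vapply(merged, `[[`, 0L, "start")
  ends <- vapply(merged, `[[`, 0L, "end")
  ord <- order(starts, ends)
  merged <- merged[ord]
  starts <- starts[ord]
  ends <- ends[ord]
  sent_idx <- vapply(starts, function(s) {
    w <- which(sentences$start <= s & s < sentences$end)
    if (length(w)) w[1L] else NA_integer_
  }, integer(1))
  out <- data.frame(doc_id = doc_id, sentence_index = sent_idx,
                    start = starts, end = ends,
                    surface = substring(text, starts + 1L, ends),
                    stringsAsFactors = FALSE)
  out$candidates <- lapply(merged, `[[`, "candidates")
  out
}

#' Harmonization configuration
#'
#' @param namespace_rank Static precedence among namespaces for exact-overlap
#'   ties when no organism cue applies (earlier wins). The defaults put human
#'   over mouse over rat gene namespaces and ChEBI over ChEMBL over the
#'   legacy chemical namespace.
#' @param organism_cues Named list mapping organisms to the document-scope
#'   cue words that select that organism's gene namespace.
#' @return A list of class `harmonize_config`.
#' @export
harmonize_config <- function(
    namespace_rank = c("HGNC", "MGI", "RGD", "SFAM", "SCOMP", "CHEBI",
                       "CHEMBL", "SCHEM", "GOBP", "MESHPP", "GOCC", "MESHD",
                       "MESHAnatomy", "CellLine", "CellStructure"),
    organism_cues = list(
      human = c("human", "humans", "patient", "patients"),
      mouse = c("mouse", "mice", "murine"),
      rat = c("rat", "rats"))) {
  structure(list(namespace_rank = namespace_rank,
                 organism_cues = organism_cues),
            class = "harmonize_config")
}

.document_organism <- function(doc_text, config) {
  toks <- tolower(.document_tokens(doc_text)$token)
  hits <- lapply(names(config$organism_cues), function(org) {
    pos <- which(toks %in% config$organism_cues[[org]])
    if (length(pos)) c(pos[1L]) else NA_integer_
  })
  names(hits) <- names(config$organism_cues)
  first <- unlist(hits)
  if (all(is.na(first))) return(NA_character_)
  names(first)[which.min(first)]
}

.select_candidate <- function(candidates, organism, rank) {
  cand <- candidates
  if (!is.na(organism) && any(cand$organism == organism))
    cand <- cand[cand$organism == organism, , drop = FALSE]
  r <- match(cand$namespace, rank)
  r[is.na(r)] <- length(rank) + 1L
  cand <- cand[order(r, cand$value, method = "radix"), , drop = FALSE]
  cand[1L, , drop = FALSE]
}

#' Harmonize overlapping mentions and select one concept each
#'
#' Mentions whose span is strictly contained in a longer surviving mention
#' are suppressed (longest match wins). For the survivors one candidate is
#' selected: if the document mentions an organism cue (whole-document scope),
#' the cued organism's gene candidate is preferred; otherwise the static
#' namespace ranking applies, with lexicographic value as the final
#' tie-break. All candidates remain available on the mention for display.
#'
#' @param mentions Output of [annotate_mentions()].
#' @param doc_text The document text the mentions refer to.
#' @param config A [harmonize_config()].
#' @return The surviving mentions with `selected_namespace`,
#'   `selected_value`, `selected_class`, `selected_organism` columns set.
#' @export
harmonize_mentions <- function(mentions, doc_text,
                               config = harmonize_config()) {
  if (nrow(mentions) == 0L) {
    out <- mentions
    out$selected_namespace <- character(0)
    out$selected_value <- character(0)
    out$selected_class <- character(0)
    out$selected_organism <- character(0)
    return(out)
  }
  n <- nrow(mentions)
  contained <- vapply(seq_len(n), function(i) {
    any(mentions$start <= mentions$start[i] & mentions$end[i] <= mentions$end &
          (mentions$end - mentions$start) >
            (mentions$end[i] - mentions$start[i]))
  }, logical(1))
  out <- mentions[!contained, , drop = FALSE]
  organism <- .document_organism(doc_text, config)
  sel <- lapply(out$candidates, .select_candidate, organism = organism,
                rank = config$namespace_rank)
  out$selected_namespace <- vapply(sel, function(s) s$namespace, character(1))
  out$selected_value <- vapply(sel, function(s) s$value, character(1))
  out$selected_class <- vapply(sel, function(s) s$entity_class, character(1))
  out$selected_organism <- vapply(sel, function(s) s$organism, character(1))
  rownames(out) <- NULL
  out
}

#' Map mentions to document-scope context annotations
#'
#' Mentions whose selected concept comes from a context-annotation namespace
#' (MeSH anatomy, cell lines, cell structures) become candidate context
#' annotations attached at document scope; gene, chemical and process
#' mentions never map.
#'
#' @param mentions Harmonized mentions.
#' @return A data.frame with columns `class` (annotation class, equal to the
#'   namespace symbol) and `value`, deduplicated.
#' @export
map_context <- function(mentions) {
  context_ns <- c("MESHAnatomy", "CellLine", "CellStructure")
  keep <- nrow(mentions) > 0 &
    mentions$selected_namespace %in% context_ns &
    mentions$selected_class %in% c("anatomy", "cell_line", "cell_structure")
  out <- data.frame(class = mentions$selected_namespace[keep],
                    value = mentions$selected_value[keep],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}
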