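# Baseline relation extraction: a trigger-lexicon event tagger and a
# co-occurrence association pairer.
#
# These are deliberately simple, deterministic stand-ins for the trained
# event-extraction and sentence-classification systems used in production
# pipelines; externally produced standoff annotations can be ingested through
# read_standoff() instead. Argument attachment uses token distance, not a
# dependency parse.

#' Default trigger lexicon
#'
#' Maps trigger stems (matched as lower-case prefixes of sentence tokens) to
#' event types. `express` is special-cased at extraction time: with a surface
#' location word nearby it yields a Localization event, otherwise
#' Gene_expression.
#'
#' @return Named character vector: stem -> event type.
#' @export
trigger_lexicon <- function() {
  c(express = "Gene_expression", transfect = "Gene_expression",
    transcription = "Transcription",
    phosphorylation = "Phosphorylation",
    degrad = "ProteinCatabolism",
    secret = "Localization", translocat = "Localization",
    localiz = "Localization",
    interact = "Binding", bind = "Binding", complex = "Binding",
    induc = "PositiveRegulation", increas = "PositiveRegulation",
    activat = "PositiveRegulation",
    decreas = "NegativeRegulation", inhibit = "NegativeRegulation",
    reduc = "NegativeRegulation",
    control = "Regulation", regulat = "Regulation")
}

.LOCATION_WORDS <- c("nuclear", "nucleus", "membrane", "surface", "cytoplasm",
                     "cytoplasmic")
.SITE_PATTERN <- "\\b(Ser|Thr|Tyr|His)-?[0-9]+\\b"

.token_type <- function(token, lexicon) {
  lower <- tolower(token)
  stems <- names(lexicon)
  hit <- stems[startsWith(lower, stems)]
  if (length(hit) == 0L) return(NA_character_)
  # longest stem wins (e.g. "transcription" over hypothetical shorter stems)
  lexicon[[hit[which.max(nchar(hit))]]]
}

# Token index of the mention (first token whose span starts inside it).
.mention_token <- function(mention_start, mention_end, toks) {
  w <- which(toks$start >= mention_start & toks$start < mention_end)
  if (length(w)) w[1L] else NA_integer_
}

.nearest <- function(pos, candidates_pos, side = c("any", "left", "right"),
                     prefer = c("right", "left")) {
  side <- match.arg(side)
  prefer <- match.arg(prefer)
  if (length(candidates_pos) == 0L) return(NA_integer_)
  d <- candidates_pos - pos
  keep <- switch(side, any = rep(TRUE, length(d)), left = d < 0, right = d > 0)
  if (!any(keep)) return(NA_integer_)
  idx <- which(keep)
  dist <- abs(d[idx])
  best <- idx[dist == min(dist)]
  if (length(best) > 1L) {
    dir <- d[best]
    best <- if (prefer == "right" && any(dir > 0)) best[dir > 0][1L]
    else if (prefer == "left" && any(dir < 0)) best[dir < 0][1L]
    else best[1L]
  }
  best
}

#' Extract events from one sentence with a trigger lexicon
#'
#' One event is proposed per trigger occurrence. For non-regulation events
#' the Theme is the nearest gene/family/complex mention by token distance
#' (Binding additionally takes the nearest eligible mention on the opposite
#' side as Theme2; phosphorylation sites are read from an `of <residue>`
#' pattern; location words fill ToLoc). Regulation events prefer another
#' event as Theme when one exists in the sentence, mirroring regulation of
#' expression/localization events, and take the nearest mention on the
#' opposite side as Cause; chemicals are eligible as regulation arguments.
#'
#' @param sentence_text The sentence.
#' @param mentions Harmonized mentions of this sentence with an `id` column;
#'   offsets must be relative to `sentence_text` (use
#'   [sentence_mentions()] to rebase document mentions).
#' @param lexicon A [trigger_lexicon()].
#' @return List of `bel_event`; empty when no trigger matches.
#' @export
extract_events <- function(sentence_text, mentions,
                           lexicon = trigger_lexicon()) {
  toks <- .document_tokens(sentence_text)
  if (nrow(toks) == 0L) return(list())
  types <- vapply(toks$token, .token_type, "", lexicon = lexicon,
                  USE.NAMES = FALSE)
  # "complex" as a trigger only counts when used as a noun near "with"/"of";
  # keep it simple: require another token, and never fire on mention-covered
  # tokens (e.g. "LPS receptor complex" as part of an entity name).
  if (nrow(mentions)) {
    covered <- vapply(seq_len(nrow(toks)), function(i)
      any(mentions$start <= toks$start[i] & toks$end[i] <= mentions$end),
      logical(1))
    types[covered] <- NA_character_
  }
  trigger_idx <- which(!is.na(types))
  if (length(trigger_idx) == 0L) return(list())

  mention_tok <- if (nrow(mentions))
    vapply(seq_len(nrow(mentions)), function(i)
      .mention_token(mentions$start[i], mentions$end[i], toks), integer(1))
  else integer(0)
  gene_like <- nrow(mentions) > 0 &
    mentions$selected_class %in% c("gene_protein", "family", "complex")
  chem_like <- nrow(mentions) > 0 & mentions$selected_class == "chemical"

  loc_idx <- which(tolower(toks$token) %in% .LOCATION_WORDS)
  span_at <- function(i) list(start = toks$start[i], end = toks$end[i],
                              text = toks$token[i])

  events <- list()
  next_id <- function() paste0("E", length(events) + 1L)
  consumed <- rep(FALSE, nrow(mentions))

  # pass 1: non-regulation events
  core_pos <- integer(0)   # trigger token index of each pass-1 event
  for (i in trigger_idx) {
    type <- types[i]
    if (type %in% REGULATION_TYPES) next
    token <- tolower(toks$token[i])
    if (type == "Gene_expression" && startsWith(token, "express") &&
        length(loc_idx) &&
        any(tolower(toks$token[loc_idx]) %in% c("surface", "membrane")))
      type <- "Localization"
    theme_row <- .nearest(i, mention_tok[which(gene_like)],
                          prefer = "left")
    if (is.na(theme_row)) next
    theme_i <- which(gene_like)[theme_row]
    theme_pos <- mention_tok[theme_i]
    ev <- list(id = next_id(), type = type, trigger = span_at(i),
               theme = mentions$id[theme_i])
    if (type == "Binding") {
      opposite <- if (theme_pos < i) "right" else "left"
      other <- setdiff(which(gene_like), theme_i)
      t2 <- .nearest(i, mention_tok[other], side = opposite)
      if (!is.na(t2)) {
        ev$theme2 <- mentions$id[other[t2]]
        consumed[other[t2]] <- TRUE
      }
    }
    if (type == "Phosphorylation") {
      m <- regexpr(.SITE_PATTERN, sentence_text)
      if (m > 0L) {
        s0 <- as.integer(m) - 1L
        ev$site <- list(start = s0, end = s0 + attr(m, "match.length"),
                        text = regmatches(sentence_text, m))
      }
    }
    if (type == "Localization" && length(loc_idx)) {
      l <- .nearest(i, loc_idx, prefer = "left")
      if (!is.na(l)) ev$to_loc <- span_at(loc_idx[l])
    }
    consumed[theme_i] <- TRUE
    events[[length(events) + 1L]] <-
      bel_event(ev$id, ev$type, ev$trigger, ev$theme, theme2 = ev$theme2,
                site = ev$site, to_loc = ev$to_loc)
    core_pos <- c(core_pos, i)
  }

  # pass 2: regulation events over pass-1 events or mentions
  reg_eligible <- gene_like | chem_like
  for (i in trigger_idx) {
    type <- types[i]
    if (!type %in% REGULATION_TYPES) next
    theme_ref <- NULL
    theme_side <- NA_character_
    if (length(core_pos)) {
      k <- .nearest(i, core_pos, prefer = "right")
      theme_ref <- events[[k]]$id
      theme_side <- if (core_pos[k] < i) "left" else "right"
    } else {
      free <- which(reg_eligible & !consumed)
      k <- .nearest(i, mention_tok[free], prefer = "right")
      if (is.na(k)) next
      theme_ref <- mentions$id[free[k]]
      theme_side <- if (mention_tok[free[k]] < i) "left" else "right"
    }
    opposite <- if (theme_side == "left") "right" else "left"
    cause_cand <- which(reg_eligible & !consumed &
                          mentions$id != theme_ref)
    c_k <- .nearest(i, mention_tok[cause_cand], side = opposite)
    cause_ref <- if (!is.na(c_k)) mentions$id[cause_cand[c_k]] else NULL
    events[[length(events) + 1L]] <-
      bel_event(next_id(), type, span_at(i), theme_ref, cause = cause_ref)
  }
  events
}

#' Rebase document mentions onto a sentence
#'
#' Filters a harmonized document mention table to one sentence and shifts
#' the offsets to be sentence-relative, assigning stable `T` ids.
#'
#' @param mentions Harmonized document mentions.
#' @param sentence One row of [split_sentences()] output.
#' @return The sentence's mentions with `id` and sentence-relative offsets.
#' @export
sentence_mentions <- function(mentions, sentence) {
  keep <- mentions$start >= sentence$start & mentions$end <= sentence$end
  out <- mentions[keep, , drop = FALSE]
  if (nrow(out)) {
    out$start <- out$start - sentence$start
    out$end <- out$end - sentence$start
    out$id <- paste0("T", seq_len(nrow(out)))
  } else {
    out$id <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Association extraction configuration
#'
#' @param cue_stems Lower-case stems; a sentence must contain a token
#'   starting with one of them for pairs to be emitted (unless
#'   `all_pairs = TRUE`).
#' @param all_pairs Emit every eligible pair regardless of cue words.
#' @return A list of class `association_config`.
#' @export
association_config <- function(
    cue_stems = c("interact", "bind", "associat", "correlat", "control",
                  "regulat", "induc", "inhibit", "increas", "decreas",
                  "reduc", "affect", "activat", "suppress"),
    all_pairs = FALSE) {
  structure(list(cue_stems = cue_stems, all_pairs = all_pairs),
            class = "association_config")
}

#' Extract co-occurrence association pairs from one sentence
#'
#' Emits all unordered pairs of eligible-class mentions (genes, families,
#' complexes, chemicals, biological processes) when the sentence contains an
#' interaction cue word, or unconditionally with `all_pairs = TRUE`. Pair
#' order follows text order; the baseline assigns score 1. The association
#' predicate carries no direction, so either member might be the true
#' subject.
#'
#' @param sentence_text The sentence.
#' @param mentions Sentence mentions with `id` (see [sentence_mentions()]).
#' @param config An [association_config()].
#' @return A data.frame with columns `entity1`, `entity2` (mention ids in
#'   text order) and `score`.
#' @export
extract_associations <- function(sentence_text, mentions,
                                 config = association_config()) {
  empty <- data.frame(entity1 = character(0), entity2 = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  eligible <- which(mentions$selected_class %in%
                      c("gene_protein", "family", "complex", "chemical",
                        "bioprocess"))
  if (length(eligible) < 2L) return(empty)
  if (!config$all_pairs) {
    toks <- tolower(.document_tokens(sentence_text)$token)
    cued <- any(vapply(toks, function(t)
      any(startsWith(t, config$cue_stems)), logical(1)))
    if (!cued) return(empty)
  }
  eligible <- eligible[order(mentions$start[eligible])]
  pairs <- utils::combn(eligible, 2L)
  data.frame(entity1 = mentions$id[pairs[1L, ]],
             entity2 = mentions$id[pairs[2L, ]],
             score = 1, stringsAsFactors = FALSE)
}
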