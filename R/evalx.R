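# Multi-level scoring of predicted vs gold BEL statements.
#
# Six levels, coarse to fine:
#   T   normalized entities (namespace:value anywhere in the statement;
#       the artificial placeholder is not a normalized entity)
#   FS  regulatory function names alone (act, pmod, deg, sec, surf, tloc,
#       complex), entity association ignored
#   F   (function, attached entity) pairs
#   RS  relationship with partial credit: a predicted triple counts when
#       subject+predicate, predicate+object or subject+object agree with an
#       unconsumed gold triple (placeholder subjects never satisfy a subject
#       match)
#   R   full (subject head, predicate, object head) triples, functions
#       stripped; nested statements contribute their inner triples as well
#   S   the full canonical statement text
# Matching is set-based, one-to-one per sentence: each predicted component
# can consume at most one gold component, with a maximum bipartite matching
# so that exact and partial credit are assigned optimally. Counts are summed
# over sentences (micro-average).

#' The six evaluation levels, coarse entities to full statements
#' @export
EVAL_LEVELS <- c("T", "FS", "F", "RS", "R", "S")

.FUNCTION_COMPONENTS <- c("act", "pmod", "deg", "sec", "surf", "tloc",
                          "complex")

.as_statement <- function(x) {
  if (inherits(x, "bel_statement")) return(bel_canonical(x))
  bel_canonical(parse_bel_statement(x))
}

.term_entities <- function(t) {
  out <- character(0)
  if (is_entity_term(t)) {
    if (t$ns != "PH") out <- paste0(t$ns, ":", t$value)
  } else {
    out <- unlist(lapply(t$args, .term_entities), use.names = FALSE)
    if (t$fn == "tloc" && !is.null(t$loc))
      out <- c(out, paste0(t$loc$ns, ":", t$loc$value))
  }
  out
}

.term_functions <- function(t) {
  out <- list()
  if (length(t$pmods)) {
    ent <- paste0(t$ns, ":", t$value)
    for (m in t$pmods) out[[length(out) + 1L]] <- c("pmod", ent)
  }
  if (t$fn %in% .FUNCTION_COMPONENTS) {
    if (is_entity_term(t)) {
      out[[length(out) + 1L]] <- c(t$fn, paste0(t$ns, ":", t$value))
    } else {
      for (a in t$args)
        out[[length(out) + 1L]] <- c(t$fn, bel_head_entity(a))
    }
  }
  for (a in t$args) out <- c(out, .term_functions(a))
  out
}

.statement_terms <- function(s) {
  obj <- if (inherits(s$object, "bel_statement"))
    .statement_terms(s$object) else list(s$object)
  c(list(s$subject), obj)
}

.statement_triples <- function(s) {
  subj <- bel_head_entity(s$subject)
  triple <- data.frame(subject = subj, predicate = s$relation,
                       object = bel_head_entity(s$object),
                       subject_placeholder = is_placeholder_term(s$subject),
                       stringsAsFactors = FALSE)
  if (inherits(s$object, "bel_statement"))
    triple <- rbind(triple, .statement_triples(s$object))
  triple
}

#' Decompose a BEL statement into its evaluation-level components
#'
#' @param statement A `bel_statement` or BEL text.
#' @return A list with elements `T` (entity strings), `FS` (function names),
#'   `F` (`"fn|entity"` strings), `R` (triple data.frame with columns
#'   `subject`, `predicate`, `object`, `subject_placeholder`), and `S` (the
#'   canonical text), each deduplicated.
#' @examples
#' decompose_statement("a(CHEBI:galangin) -> act(p(HGNC:AHR))")
#' @export
decompose_statement <- function(statement) {
  s <- .as_statement(statement)
  terms <- .statement_terms(s)
  funcs <- do.call(c, lapply(terms, .term_functions))
  f_pairs <- unique(vapply(funcs, function(x) paste(x, collapse = "|"),
                           character(1)))
  list(T = unique(unlist(lapply(terms, .term_entities), use.names = FALSE)),
       FS = unique(vapply(funcs, `[[`, "", 1L)),
       F = f_pairs,
       R = unique(.statement_triples(s)),
       S = bel_text(s))
}

.sentence_components <- function(statements, level) {
  decs <- lapply(statements, decompose_statement)
  if (level == "R" || level == "RS") {
    tri <- do.call(rbind, c(list(data.frame(subject = character(0),
                                            predicate = character(0),
                                            object = character(0),
                                            subject_placeholder = logical(0),
                                            stringsAsFactors = FALSE)),
                            lapply(decs, `[[`, "R")))
    tri <- unique(tri)
    rownames(tri) <- NULL
    return(tri)
  }
  unique(unlist(lapply(decs, `[[`, level), use.names = FALSE))
}

.triple_key <- function(tri) {
  paste(tri$subject, tri$predicate, tri$object, sep = "\r")
}

# Maximum one-to-one matching between n_left predicted and n_right gold
# components under the `allowed(i, j)` relation (Kuhn's augmenting-path
# algorithm). Sizes are per-sentence component counts, so this stays tiny.
.max_bipartite <- function(n_left, n_right, allowed) {
  match_right <- rep(NA_integer_, n_right)
  try_augment <- function(i, seen) {
    for (j in seq_len(n_right)) {
      if (seen[j] || !allowed(i, j)) next
      seen[j] <- TRUE
      if (is.na(match_right[j]) ||
          Recall(match_right[j], seen)) {
        match_right[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_len(n_left)) {
    if (try_augment(i, rep(FALSE, n_right))) size <- size + 1L
  }
  size
}

.partial_match <- function(p, g) {
  subj_eq <- !p$subject_placeholder && !g$subject_placeholder &&
    p$subject == g$subject
  pred_eq <- p$predicate == g$predicate
  obj_eq <- p$object == g$object
  (subj_eq && pred_eq) || (pred_eq && obj_eq) || (subj_eq && obj_eq)
}

#' Match gold against predicted statements at one level (one sentence)
#'
#' @param gold,predicted Character vectors of BEL statements (or lists of
#'   `bel_statement`) from the same sentence.
#' @param level One of `"T"`, `"FS"`, `"F"`, `"RS"`, `"R"`, `"S"`.
#' @return Named integer vector `c(tp =, fp =, fn =)`.
#' @export
match_statements <- function(gold, predicted, level) {
  if (!level %in% EVAL_LEVELS)
    stop("unknown evaluation level '", level, "'", call. = FALSE)
  gold_c <- .sentence_components(as.list(gold), level)
  pred_c <- .sentence_components(as.list(predicted), level)
  if (level %in% c("T", "FS", "F", "S")) {
    tp <- length(intersect(pred_c, gold_c))
    return(c(tp = tp, fp = length(pred_c) - tp, fn = length(gold_c) - tp))
  }
  gkeys <- .triple_key(gold_c)
  pkeys <- .triple_key(pred_c)
  allowed <- function(i, j) {
    if (pkeys[i] == gkeys[j]) return(TRUE)
    level == "RS" && .partial_match(pred_c[i, ], gold_c[j, ])
  }
  tp <- .max_bipartite(length(pkeys), length(gkeys), allowed)
  c(tp = tp, fp = length(pkeys) - tp, fn = length(gkeys) - tp)
}

#' Precision, recall and F-score from counts
#'
#' Precision is `TP/(TP+FP)` and recall `TP/(TP+FN)`, both defined as 1 when
#' their denominator is 0; the F-score is their harmonic mean, 0 when both
#' are 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision =, recall =, f_score =)` as
#'   fractions in `[0, 1]`.
#' @export
score_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0
  else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f_score = f)
}

.read_statement_tsv <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sentence_id", "statement") %in% names(x)))
    return(x[, c("sentence_id", "statement")])
  }
  df <- utils::read.delim(x, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  stopifnot(all(c("sentence_id", "statement") %in% names(df)))
  df[, c("sentence_id", "statement")]
}

#' Evaluate predicted against gold statements at all six levels
#'
#' Inputs are statement tables (`sentence_id`, `statement`) or paths to TSV
#' files with those columns. Sentences present only in the gold set
#' contribute false negatives; sentences present only in the predictions
#' contribute false positives. Counts are micro-averaged over sentences.
#'
#' @param gold,predicted Statement tables or TSV paths.
#' @param dedupe Drop duplicate canonical statements within a sentence
#'   before matching (default `TRUE`; matching is set-based either way).
#' @return A data.frame of class `bel_eval_report` with one row per level
#'   (`T`, `FS`, `F`, `RS`, `R`, `S`) and columns `TP`, `FP`, `FN`,
#'   `precision`, `recall`, `f_score` (percentages).
#' @export
evaluate_statements <- function(gold, predicted, dedupe = TRUE) {
  g <- .read_statement_tsv(gold)
  p <- .read_statement_tsv(predicted)
  check_parse <- function(df, label) {
    for (i in seq_len(nrow(df))) {
      ok <- tryCatch({parse_bel_statement(df$statement[i]); TRUE},
                     bel_syntax_error = function(e) FALSE)
      if (!ok)
        stop("unparseable ", label, " statement for sentence ",
             df$sentence_id[i], ": ", df$statement[i], call. = FALSE)
    }
  }
  check_parse(g, "gold")
  check_parse(p, "predicted")
  ids <- union(g$sentence_id, p$sentence_id)
  totals <- matrix(0L, nrow = length(EVAL_LEVELS), ncol = 3L,
                   dimnames = list(EVAL_LEVELS, c("tp", "fp", "fn")))
  for (id in ids) {
    gs <- g$statement[g$sentence_id == id]
    ps <- p$statement[p$sentence_id == id]
    if (dedupe) {
      gs <- unique(vapply(gs, bel_canonical_text, "", USE.NAMES = FALSE))
      ps <- unique(vapply(ps, bel_canonical_text, "", USE.NAMES = FALSE))
    }
    for (lev in EVAL_LEVELS)
      totals[lev, ] <- totals[lev, ] + match_statements(gs, ps, lev)
  }
  scores <- t(apply(totals, 1L, function(x)
    score_counts(x[["tp"]], x[["fp"]], x[["fn"]])))
  report <- data.frame(level = EVAL_LEVELS,
                       TP = totals[, "tp"], FP = totals[, "fp"],
                       FN = totals[, "fn"],
                       precision = round(100 * scores[, "precision"], 2),
                       recall = round(100 * scores[, "recall"], 2),
                       f_score = round(100 * scores[, "f_score"], 2),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  class(report) <- c("bel_eval_report", "data.frame")
  report
}

#' @export
print.bel_eval_report <- function(x, ...) {
  labels <- c(T = "Term (T)", FS = "Function-Secondary (FS)",
              F = "Function (F)", RS = "Relationship-Secondary (RS)",
              R = "Relationship (R)", S = "Statement (S)")
  cat(sprintf("%-28s %4s %4s %4s %10s %8s %8s\n", "Class", "TP", "FP", "FN",
              "Precision", "Recall", "F-score"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-28s %4d %4d %4d %10.2f %8.2f %8.2f\n",
                labels[[x$level[i]]], x$TP[i], x$FP[i], x$FN[i],
                x$precision[i], x$recall[i], x$f_score[i]))
  invisible(x)
}

#' Classify each predicted statement against the gold standard
#'
#' Statement-level labels for curator-facing display, with one-to-one
#' consumption of the gold standard: predictions whose canonical text equals
#' an unconsumed gold statement are `"TP"`; the remaining predictions are
#' matched (maximum matching) onto the remaining gold relationship triples,
#' a prediction counting as `"partial"` when one of its triples exactly or
#' partially matches a triple it is assigned to; everything else is `"FP"`.
#'
#' @param gold,predicted Character vectors of BEL statements from one
#'   sentence.
#' @return Character vector of labels, one per predicted statement.
#' @export
classify_predictions <- function(gold, predicted) {
  gold_s <- vapply(gold, bel_canonical_text, "", USE.NAMES = FALSE)
  pred_s <- vapply(predicted, bel_canonical_text, "", USE.NAMES = FALSE)
  labels <- rep(NA_character_, length(predicted))
  gold_consumed <- rep(FALSE, length(gold))
  for (i in seq_along(pred_s)) {
    hit <- which(!gold_consumed & gold_s == pred_s[i])
    if (length(hit)) {
      labels[i] <- "TP"
      gold_consumed[hit[1L]] <- TRUE
    }
  }
  open_gold <- which(!gold_consumed)
  gold_tri <- if (length(open_gold))
    .sentence_components(as.list(gold[open_gold]), "R")
  else .sentence_components(list(), "R")
  open_pred <- which(is.na(labels))
  pred_tri <- lapply(open_pred, function(i) decompose_statement(predicted[[i]])$R)
  allowed <- function(a, b) {
    tri <- pred_tri[[a]]
    g <- gold_tri[b, ]
    for (k in seq_len(nrow(tri))) {
      p <- tri[k, ]
      if (.triple_key(p) == .triple_key(g) || .partial_match(p, g))
        return(TRUE)
    }
    FALSE
  }
  if (length(open_pred) && nrow(gold_tri)) {
    match_right <- rep(NA_integer_, nrow(gold_tri))
    try_augment <- function(a, seen) {
      for (b in seq_len(nrow(gold_tri))) {
        if (seen[b] || !allowed(a, b)) next
        seen[b] <- TRUE
        if (is.na(match_right[b]) || Recall(match_right[b], seen)) {
          match_right[b] <<- a
          return(TRUE)
        }
      }
      FALSE
    }
    for (a in seq_along(open_pred)) {
      if (try_augment(a, rep(FALSE, nrow(gold_tri))))
        labels[open_pred[a]] <- "partial"
    }
  }
  labels[is.na(labels)] <- "FP"
  labels
}
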