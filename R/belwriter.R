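# Translation of events and association pairs into BEL.
#
# Rules implemented (by event type):
#   Gene_expression / Transcription -> bare entity term; protein abundance
#     p() for triggers stemming from "express", RNA abundance r() otherwise
#     and for all Transcription events
#   Phosphorylation -> p(NS:value, pmod(P[, residue, position])), the site
#     parsed from forms such as "Thr-426"
#   ProteinCatabolism -> deg(term)
#   Localization -> sec(term) for "secret*" triggers; surf(term) for
#     "express*" triggers or a (cell) surface location argument;
#     tloc(term, GOCC:concept) otherwise, the concept looked up in the
#     location map (unmapped location text is an error for the curator)
#   Binding -> complex(term, term2)
#   PositiveRegulation / NegativeRegulation / Regulation -> statement with
#     predicate -> / -| / --; subject from Cause, object from Theme (a term,
#     or a nested statement when the Theme is itself a regulation event);
#     a missing Cause yields the artificial placeholder subject
#     a(PH:placeholder), which must be replaced before export
#   Association pair -> term1 -- term2 in text order
#
# Activity functions act() are parsed, validated and scored but never
# produced here.

#' Translation rule set
#'
#' @param regulation_map Event type -> predicate.
#' @param residue_map Three-letter -> one-letter amino-acid codes used when
#'   parsing phosphorylation sites.
#' @param location_map Lower-cased location word -> GOCC concept name.
#'   Location text absent from the map is a translation error rather than a
#'   guess.
#' @param placeholder Subject term inserted when a regulation has no Cause.
#' @return A list of class `bel_ruleset`.
#' @export
bel_ruleset <- function(
    regulation_map = c(PositiveRegulation = "->",
                       NegativeRegulation = "-|",
                       Regulation = "--"),
    residue_map = c(Ser = "S", Thr = "T", Tyr = "Y", His = "H"),
    location_map = c(nuclear = "Nucleus", nucleus = "Nucleus",
                     membrane = "plasma membrane"),
    placeholder = bel_term("a", ns = "PH", value = "placeholder")) {
  structure(list(regulation_map = regulation_map,
                 residue_map = residue_map,
                 location_map = location_map,
                 placeholder = placeholder),
            class = "bel_ruleset")
}

.mention_concept <- function(mention) {
  # accepts either a harmonized mention row (data.frame) or a light record
  # list(ns =, value =, entity_class =)
  if (is.data.frame(mention)) {
    if (nrow(mention) != 1L || is.na(mention$selected_namespace))
      stop("mention has no selected concept", call. = FALSE)
    list(ns = mention$selected_namespace, value = mention$selected_value,
         class = mention$selected_class)
  } else {
    if (is.null(mention$ns) || is.null(mention$value))
      stop("mention has no selected concept", call. = FALSE)
    list(ns = mention$ns, value = mention$value,
         class = if (!is.null(mention$entity_class)) mention$entity_class
         else "gene_protein")
  }
}

#' Default BEL term for a mention
#'
#' Chemicals always get the simple abundance `a()`; genes, protein families
#' and named complexes get protein abundance `p()` by default, switched to
#' RNA abundance `r()` under a Transcription event or a Gene_expression
#' event whose trigger does not stem from "express"; biological processes
#' get `bp()`.
#'
#' @param mention A harmonized mention row, or a record with `ns`, `value`,
#'   `entity_class`.
#' @param event_type,trigger Optional event context steering the
#'   protein-vs-RNA choice.
#' @return A `bel_term`.
#' @export
term_for_mention <- function(mention, event_type = NULL, trigger = NULL) {
  con <- .mention_concept(mention)
  fn <- switch(con$class,
               chemical = "a",
               bioprocess = "bp",
               gene_protein = "p", family = "p", complex = "p",
               stop("no abundance function for entity class '", con$class,
                    "'", call. = FALSE))
  if (fn == "p" && !is.null(event_type)) {
    if (event_type == "Transcription" ||
        (event_type == "Gene_expression" &&
           !startsWith(tolower(trigger %||% ""), "express")))
      fn <- "r"
  }
  bel_term(fn, ns = con$ns, value = con$value)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.site_pmod <- function(site_text, ruleset) {
  if (is.null(site_text)) return(bel_pmod(type = "P"))
  m <- regmatches(site_text,
                  regexec("^([A-Za-z]{1,3})-?([0-9]+)$", site_text))[[1L]]
  if (length(m) == 0L) return(bel_pmod(type = "P"))
  res <- m[2L]
  one <- if (nchar(res) == 1L) toupper(res)
  else unname(ruleset$residue_map[res])
  if (is.null(one) || is.na(one))
    stop("unknown residue '", res, "' in site \"", site_text, "\"",
         call. = FALSE)
  bel_pmod(type = "P", residue = one, position = as.integer(m[3L]))
}

.arg_text <- function(span) {
  if (is.null(span)) return(NULL)
  if (is.character(span)) span else span$text
}

#' Translate one event into a BEL term or statement
#'
#' Arguments must be resolved: event Theme/Theme2/Cause references are the
#' mention records (or nested event records) themselves, as produced by
#' [resolve_events()] or constructed directly. Regulation events yield
#' statements; all other event types yield terms.
#'
#' @param event A list with `type`, `trigger` (string or span), `theme`,
#'   and optionally `theme2`, `cause`, `site`, `to_loc`, `at_loc`, where
#'   theme/cause slots hold mention records or nested event lists.
#' @param ruleset A [bel_ruleset()].
#' @return A `bel_term` or `bel_statement`.
#' @export
event_to_bel <- function(event, ruleset = bel_ruleset()) {
  type <- event$type
  trigger <- .arg_text(event$trigger) %||% ""
  theme_is_event <- !is.null(event$theme$type)

  if (type %in% names(ruleset$regulation_map)) {
    object <- if (theme_is_event) event_to_bel(event$theme, ruleset)
    else term_for_mention(event$theme)
    if (inherits(object, "bel_statement") &&
        !event$theme$type %in% names(ruleset$regulation_map))
      stop("unexpected nested statement from non-regulation theme",
           call. = FALSE)
    subject <- if (is.null(event$cause)) {
      ruleset$placeholder
    } else if (!is.null(event$cause$type)) {
      stop("nested statements are only supported on the object side; ",
           "a regulation Cause must be an entity mention", call. = FALSE)
    } else {
      term_for_mention(event$cause)
    }
    return(bel_statement(subject, ruleset$regulation_map[[type]], object))
  }

  if (theme_is_event)
    stop("only regulation events may take another event as Theme",
         call. = FALSE)

  switch(type,
         Gene_expression = ,
         Transcription = term_for_mention(event$theme, type, trigger),
         Phosphorylation = {
           t <- term_for_mention(event$theme)
           t$pmods <- list(.site_pmod(.arg_text(event$site), ruleset))
           t
         },
         ProteinCatabolism =
           bel_term("deg", args = list(term_for_mention(event$theme))),
         Localization = {
           inner <- term_for_mention(event$theme)
           loc_text <- tolower(.arg_text(event$to_loc) %||%
                                 .arg_text(event$at_loc) %||% "")
           if (startsWith(tolower(trigger), "secret")) {
             bel_term("sec", args = list(inner))
           } else if (startsWith(tolower(trigger), "express") ||
                      loc_text %in% c("surface", "cell surface")) {
             bel_term("surf", args = list(inner))
           } else if (!nzchar(loc_text)) {
             bel_term("tloc", args = list(inner))
           } else {
             concept <- unname(ruleset$location_map[loc_text])
             if (is.na(concept))
               stop("no GOCC mapping for location \"", loc_text,
                    "\"; add it to the rule set or curate manually",
                    call. = FALSE)
             bel_term("tloc", args = list(inner),
                      loc = list(ns = "GOCC", value = concept))
           }
         },
         Binding = {
           members <- list(term_for_mention(event$theme))
           if (!is.null(event$theme2))
             members <- c(members, list(term_for_mention(event$theme2)))
           if (length(members) == 0L)
             stop("Binding event without any theme", call. = FALSE)
           bel_term("complex", args = members)
         },
         stop("unknown event type '", type, "'", call. = FALSE))
}

#' Translate an undirected association pair into a BEL statement
#'
#' @param pair List with `entity1`, `entity2` mention records (text order).
#' @param ruleset A [bel_ruleset()].
#' @return A `bel_statement` with the association predicate `--`.
#' @export
association_to_bel <- function(pair, ruleset = bel_ruleset()) {
  bel_statement(term_for_mention(pair$entity1), "--",
                term_for_mention(pair$entity2))
}

#' Resolve event argument references against mentions and sibling events
#'
#' Standoff-style events reference their arguments by id; translation wants
#' the records themselves. Produces plain event records whose `theme`,
#' `theme2` and `cause` slots hold mention concept records or nested event
#' records.
#'
#' @param events List of `bel_event` (id-referenced).
#' @param mentions Mention table with `id` and `selected_*` columns.
#' @return List of resolved event records (same order and ids).
#' @export
resolve_events <- function(events, mentions) {
  by_id <- stats::setNames(events, vapply(events, `[[`, "", "id"))
  resolve_ref <- function(ref) {
    if (is.null(ref)) return(NULL)
    if (startsWith(ref, "E")) return(resolve_one(by_id[[ref]]))
    row <- mentions[mentions$id == ref, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("unresolved mention reference ", ref, call. = FALSE)
    list(ns = row$selected_namespace, value = row$selected_value,
         entity_class = row$selected_class, surface = row$surface)
  }
  resolve_one <- function(e) {
    list(id = e$id, type = e$type, trigger = e$trigger,
         theme = resolve_ref(e$theme), theme2 = resolve_ref(e$theme2),
         cause = resolve_ref(e$cause), site = e$site, to_loc = e$to_loc,
         at_loc = e$at_loc)
  }
  lapply(events, resolve_one)
}

#' Translate a sentence's events and pairs into proposed statements
#'
#' Every regulation event and every association pair yields one statement;
#' bare terms from unregulated events (expression, binding, ...) are not
#' statements and are not emitted. Statements whose canonical text is
#' identical are deduplicated; no deeper redundancy filtering is attempted.
#'
#' @param events Resolved event records (see [resolve_events()]).
#' @param pairs Association pairs with resolved `entity1`/`entity2` records,
#'   or the id-based data.frame from [extract_associations()] together with
#'   `mentions`.
#' @param sentence_text Evidence sentence attached to each statement.
#' @param ruleset A [bel_ruleset()].
#' @param mentions Optional mention table for resolving id-based pairs.
#' @return A data.frame with columns `statement` (canonical text), `evidence`
#'   and `origin` (`"event"` or `"association"`).
#' @export
translate_sentence <- function(events, pairs = NULL, sentence_text = "",
                               ruleset = bel_ruleset(), mentions = NULL) {
  out <- list()
  for (e in events) {
    if (!e$type %in% names(ruleset$regulation_map)) next
    node <- tryCatch(event_to_bel(e, ruleset), error = function(err) NULL)
    if (is.null(node)) next
    out[[length(out) + 1L]] <- list(statement = bel_text(node),
                                    origin = "event")
  }
  if (!is.null(pairs)) {
    if (is.data.frame(pairs)) {
      stopifnot(!is.null(mentions))
      pairs <- lapply(seq_len(nrow(pairs)), function(i) {
        ref <- function(id) {
          row <- mentions[mentions$id == id, , drop = FALSE]
          list(ns = row$selected_namespace, value = row$selected_value,
               entity_class = row$selected_class)
        }
        list(entity1 = ref(pairs$entity1[i]), entity2 = ref(pairs$entity2[i]))
      })
    }
    for (p in pairs) {
      node <- tryCatch(association_to_bel(p, ruleset),
                       error = function(err) NULL)
      if (is.null(node)) next
      out[[length(out) + 1L]] <- list(statement = bel_text(node),
                                      origin = "association")
    }
  }
  if (length(out) == 0L)
    return(data.frame(statement = character(0), evidence = character(0),
                      origin = character(0), stringsAsFactors = FALSE))
  df <- data.frame(statement = vapply(out, `[[`, "", "statement"),
                   evidence = sentence_text,
                   origin = vapply(out, `[[`, "", "origin"),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df$statement), , drop = FALSE]
  rownames(df) <- NULL
  df
}
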