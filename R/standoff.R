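# BioNLP shared-task standoff input/output.
#
# .a1 files carry entity mentions (T-lines), .a2 files carry event triggers
# (T-lines) and events (E-lines). Offsets are 0-based half-open in the file
# format, matching the package's internal convention, so no conversion is
# needed. Candidate concepts, which the standoff format cannot carry, travel
# in a sidecar TSV when mentions are exported.

#' Supported BioNLP-ST event types
#' @export
EVENT_TYPES <- c("Gene_expression", "Transcription", "Phosphorylation",
                 "ProteinCatabolism", "Localization", "Binding",
                 "PositiveRegulation", "NegativeRegulation", "Regulation")
#' Event types that translate to BEL statements (they carry a Cause)
#' @export
REGULATION_TYPES <- c("PositiveRegulation", "NegativeRegulation", "Regulation")

#' Construct a BioNLP-ST event
#'
#' @param id Event identifier (`"E1"`, ...).
#' @param type One of the nine supported event types.
#' @param trigger `list(start, end, text)` for the trigger word (0-based
#'   half-open offsets).
#' @param theme Reference to the Theme: a mention id (`"T..."`) or event id
#'   (`"E..."`). Always required.
#' @param theme2 Second binding partner (Binding events only).
#' @param cause Cause reference (regulation events only).
#' @param site,to_loc,at_loc Optional argument spans, each
#'   `list(start, end, text)` or `NULL`.
#' @return An object of class `bel_event`.
#' @export
bel_event <- function(id, type, trigger, theme, theme2 = NULL, cause = NULL,
                      site = NULL, to_loc = NULL, at_loc = NULL) {
  if (!type %in% EVENT_TYPES)
    stop("unknown event type '", type, "'", call. = FALSE)
  if (is.null(theme)) stop("event requires a Theme", call. = FALSE)
  if (!is.null(theme2) && type != "Binding")
    stop("Theme2 is only valid for Binding events", call. = FALSE)
  if (!is.null(cause) && !type %in% REGULATION_TYPES)
    stop("Cause is only valid for regulation events", call. = FALSE)
  structure(list(id = id, type = type, trigger = trigger, theme = theme,
                 theme2 = theme2, cause = cause, site = site,
                 to_loc = to_loc, at_loc = at_loc),
            class = "bel_event")
}

#' @export
print.bel_event <- function(x, ...) {
  args <- c(Theme = x$theme,
            if (!is.null(x$theme2)) c(Theme2 = x$theme2),
            if (!is.null(x$cause)) c(Cause = x$cause))
  cat("<bel_event> ", x$id, " ", x$type, ":", x$trigger$text, " ",
      paste(names(args), args, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

# Detect reference cycles among events; stops on the first one found.
.check_event_cycles <- function(events) {
  refs <- lapply(events, function(e)
    grep("^E", c(e$theme, e$theme2, e$cause), value = TRUE))
  names(refs) <- vapply(events, `[[`, "", "id")
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack)
      stop("event reference cycle involving ", id, call. = FALSE)
    if (isTRUE(state[[id]])) return(invisible())
    for (r in refs[[id]]) visit(r, c(stack, id))
    state[[id]] <- TRUE
  }
  for (id in names(refs)) visit(id, character(0))
  invisible(events)
}

.parse_t_line <- function(line, lineno, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) < 3L)
    stop("malformed T-line at ", file, ":", lineno, call. = FALSE)
  mid <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
  if (length(mid) != 3L || is.na(suppressWarnings(as.integer(mid[2L]))))
    stop("malformed offset at ", file, ":", lineno, call. = FALSE)
  list(id = parts[1L], class = mid[1L], start = as.integer(mid[2L]),
       end = as.integer(mid[3L]), text = parts[3L])
}

#' Read BioNLP-ST standoff annotations
#'
#' @param txt_path Document text file.
#' @param a1_path Entity mention file (T-lines).
#' @param a2_path Event file (trigger T-lines and E-lines); may be missing or
#'   empty for documents without events.
#' @param dict Optional `bel_dictionary` used to attach candidate concepts to
#'   the mentions (the standoff format itself carries only the entity class).
#' @return A list with `text`, `mentions` (mention data.frame; the T id is in
#'   column `id`) and `events` (list of `bel_event`). Dangling argument
#'   references raise an error.
#' @export
read_standoff <- function(txt_path, a1_path, a2_path = NULL, dict = NULL) {
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  a1_lines <- readLines(a1_path, encoding = "UTF-8", warn = FALSE)
  a1_lines <- a1_lines[nzchar(a1_lines)]
  t_recs <- lapply(seq_along(a1_lines), function(i)
    .parse_t_line(a1_lines[i], i, a1_path))
  sentences <- split_sentences(text)
  mention_ids <- vapply(t_recs, `[[`, "", "id")
  starts <- vapply(t_recs, `[[`, 0L, "start")
  mentions <- data.frame(
    id = mention_ids,
    doc_id = basename(txt_path),
    sentence_index = vapply(starts, function(s) {
      w <- which(sentences$start <= s & s < sentences$end)
      if (length(w)) w[1L] else NA_integer_
    }, integer(1)),
    start = starts,
    end = vapply(t_recs, `[[`, 0L, "end"),
    surface = vapply(t_recs, `[[`, "", "text"),
    class = vapply(t_recs, `[[`, "", "class"),
    stringsAsFactors = FALSE)
  if (!is.null(dict))
    mentions$candidates <- lapply(mentions$surface, dict_lookup, dict = dict)
  events <- list()
  trigger_recs <- list()
  if (!is.null(a2_path) && file.exists(a2_path)) {
    a2_lines <- readLines(a2_path, encoding = "UTF-8", warn = FALSE)
    a2_lines <- a2_lines[nzchar(a2_lines)]
    for (i in seq_along(a2_lines)) {
      line <- a2_lines[i]
      if (startsWith(line, "T")) {
        rec <- .parse_t_line(line, i, a2_path)
        trigger_recs[[rec$id]] <- rec
      }
    }
    known_t <- c(mention_ids, names(trigger_recs))
    e_ids <- character(0)
    e_specs <- list()
    for (i in seq_along(a2_lines)) {
      line <- a2_lines[i]
      if (!startsWith(line, "E")) next
      parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 2L)
        stop("malformed E-line at ", a2_path, ":", i, call. = FALSE)
      fields <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
      head_kv <- strsplit(fields[1L], ":", fixed = TRUE)[[1L]]
      spec <- list(id = parts[1L], type = head_kv[1L],
                   trigger_id = head_kv[2L], args = list())
      for (f in fields[-1L]) {
        kv <- strsplit(f, ":", fixed = TRUE)[[1L]]
        spec$args[[kv[1L]]] <- kv[2L]
      }
      e_ids <- c(e_ids, spec$id)
      e_specs[[length(e_specs) + 1L]] <- spec
    }
    for (spec in e_specs) {
      if (!spec$trigger_id %in% names(trigger_recs))
        stop("event ", spec$id, " references unknown trigger ",
             spec$trigger_id, call. = FALSE)
      for (ref in unlist(spec$args))
        if (!ref %in% c(known_t, e_ids))
          stop("event ", spec$id, " references unknown annotation ", ref,
               call. = FALSE)
      trig <- trigger_recs[[spec$trigger_id]]
      span_of <- function(name) {
        ref <- spec$args[[name]]
        if (is.null(ref)) return(NULL)
        rec <- trigger_recs[[ref]]
        if (is.null(rec)) {
          row <- mentions[mentions$id == ref, , drop = FALSE]
          rec <- list(start = row$start, end = row$end, text = row$surface)
        }
        list(start = rec$start, end = rec$end, text = rec$text)
      }
      events[[length(events) + 1L]] <- bel_event(
        id = spec$id, type = spec$type,
        trigger = list(start = trig$start, end = trig$end, text = trig$text),
        theme = spec$args[["Theme"]],
        theme2 = spec$args[["Theme2"]],
        cause = spec$args[["Cause"]],
        site = span_of("Site"), to_loc = span_of("ToLoc"),
        at_loc = span_of("AtLoc"))
    }
    .check_event_cycles(events)
  }
  list(text = text, mentions = mentions, events = events)
}

#' Write BioNLP-ST standoff annotations
#'
#' Inverse of [read_standoff()]: `read_standoff()` on the written files
#' reproduces the mention table and event list.
#'
#' @param mentions Mention data.frame with columns `id`, `start`, `end`,
#'   `surface` and either `class` or `selected_class`.
#' @param events List of `bel_event`.
#' @param txt,a1_path,a2_path Output paths for the document text and the two
#'   annotation files.
#' @param text Document text to write to `txt`.
#' @return Invisibly, a list with the `a1` and `a2` file contents.
#' @export
write_standoff <- function(mentions, events, text, txt, a1_path, a2_path) {
  cls <- if ("class" %in% names(mentions)) mentions$class
  else mentions$selected_class
  a1 <- sprintf("%s\t%s %d %d\t%s", mentions$id, cls, mentions$start,
                mentions$end, mentions$surface)
  a2 <- character(0)
  trig_id <- 0L
  trig_lines <- character(0)
  ev_lines <- character(0)
  trig_key <- character(0)
  trig_ids <- character(0)
  arg_spans <- list()
  span_ref <- function(span, class) {
    key <- paste(class, span$start, span$end)
    hit <- match(key, trig_key)
    if (!is.na(hit)) return(trig_ids[hit])
    trig_id <<- trig_id + 1L
    id <- paste0("T", 1000L + trig_id)
    trig_key <<- c(trig_key, key)
    trig_ids <<- c(trig_ids, id)
    trig_lines <<- c(trig_lines,
                     sprintf("%s\t%s %d %d\t%s", id, class, span$start,
                             span$end, span$text))
    id
  }
  for (e in events) {
    trig <- span_ref(e$trigger, e$type)
    fields <- c(paste0(e$type, ":", trig), paste0("Theme:", e$theme))
    if (!is.null(e$theme2)) fields <- c(fields, paste0("Theme2:", e$theme2))
    if (!is.null(e$cause)) fields <- c(fields, paste0("Cause:", e$cause))
    if (!is.null(e$site))
      fields <- c(fields, paste0("Site:", span_ref(e$site, "Entity")))
    if (!is.null(e$to_loc))
      fields <- c(fields, paste0("ToLoc:", span_ref(e$to_loc, "Entity")))
    if (!is.null(e$at_loc))
      fields <- c(fields, paste0("AtLoc:", span_ref(e$at_loc, "Entity")))
    ev_lines <- c(ev_lines, paste0(e$id, "\t", paste(fields, collapse = " ")))
  }
  a2 <- c(trig_lines, ev_lines)
  writeLines(text, txt, useBytes = TRUE)
  writeLines(a1, a1_path, useBytes = TRUE)
  writeLines(a2, a2_path, useBytes = TRUE)
  invisible(list(a1 = a1, a2 = a2))
}
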