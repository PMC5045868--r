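# Dictionary / namespace resources.
#
# A dictionary maps controlled-vocabulary concepts (namespace + preferred
# name) to entity classes, organisms and synonym lists. One dictionary object
# can hold entries from many namespaces; the NER treats each namespace as an
# independent matching dictionary. The on-disk format is a headered TSV with
# columns: namespace, value, entity_class, organism, synonyms
# (pipe-separated).

ENTITY_CLASSES <- c("gene_protein", "family", "complex", "bioprocess",
                    "chemical", "disease", "anatomy", "cell_line",
                    "cell_structure")
ORGANISMS <- c("human", "mouse", "rat", "none")

#' Construct a dictionary from an entry table
#'
#' Duplicate `(namespace, value)` rows are merged with their synonym lists
#' unioned. The preferred name always counts as a synonym.
#'
#' @param entries A data.frame with columns `namespace`, `value`,
#'   `entity_class`, `organism` and a list-column `synonyms` (or a character
#'   column of pipe-separated synonyms).
#' @return An object of class `bel_dictionary`.
#' @export
bel_dictionary <- function(entries) {
  stopifnot(is.data.frame(entries))
  needed <- c("namespace", "value", "entity_class", "organism", "synonyms")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols))
    stop("dictionary is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.list(entries$synonyms))
    entries$synonyms <- strsplit(as.character(entries$synonyms), "|",
                                 fixed = TRUE)
  bad_class <- setdiff(unique(entries$entity_class), ENTITY_CLASSES)
  if (length(bad_class))
    stop("unknown entity_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  bad_org <- setdiff(unique(entries$organism), ORGANISMS)
  if (length(bad_org))
    stop("unknown organism: ", paste(bad_org, collapse = ", "), call. = FALSE)
  off <- entries$organism != "none" & entries$entity_class != "gene_protein"
  if (any(off))
    stop("organism may only be set for gene_protein entries (row ",
         which(off)[1L], ")", call. = FALSE)
  key <- paste(entries$namespace, entries$value, sep = "\r")
  merged <- entries[!duplicated(key), , drop = FALSE]
  merged$synonyms <- lapply(unique(key), function(k) {
    rows <- which(key == k)
    unique(c(entries$value[rows[1L]],
             unlist(entries$synonyms[rows], use.names = FALSE)))
  })
  rownames(merged) <- NULL
  structure(list(entries = merged), class = "bel_dictionary")
}

#' @export
print.bel_dictionary <- function(x, ...) {
  cat("<bel_dictionary> ", nrow(x$entries), " entries across ",
      length(unique(x$entries$namespace)), " namespaces\n", sep = "")
  invisible(x)
}

#' Read a dictionary from a TSV file
#'
#' @param path Path to a headered TSV with columns `namespace`, `value`,
#'   `entity_class`, `organism`, `synonyms` (pipe-separated).
#' @return A `bel_dictionary`. An empty file (header only, or zero bytes)
#'   yields an empty dictionary.
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_dictionary())
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  needed <- c("namespace", "value", "entity_class", "organism", "synonyms")
  if (!identical(header[seq_along(needed)], needed))
    stop("dictionary header must be: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (length(lines) == 1L) return(empty_dictionary())
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 5L))
    stop("malformed dictionary row at line ", which(nf < 5L)[1L] + 1L,
         ": expected 5 tab-separated fields", call. = FALSE)
  df <- data.frame(namespace = vapply(rows, `[[`, "", 1L),
                   value = vapply(rows, `[[`, "", 2L),
                   entity_class = vapply(rows, `[[`, "", 3L),
                   organism = vapply(rows, `[[`, "", 4L),
                   stringsAsFactors = FALSE)
  df$synonyms <- lapply(rows, function(r) {
    s <- strsplit(r[[5L]], "|", fixed = TRUE)[[1L]]
    s[nzchar(s)]
  })
  bel_dictionary(df)
}

#' Write a dictionary to TSV
#'
#' @param dict A `bel_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  e <- dict$entries
  lines <- c(paste(c("namespace", "value", "entity_class", "organism",
                     "synonyms"), collapse = "\t"),
             paste(e$namespace, e$value, e$entity_class, e$organism,
                   vapply(e$synonyms, paste, "", collapse = "|"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

empty_dictionary <- function() {
  bel_dictionary(data.frame(namespace = character(0), value = character(0),
                            entity_class = character(0),
                            organism = character(0),
                            synonyms = I(list())))
}

dict_namespaces <- function(dict) unique(dict$entries$namespace)

dict_find <- function(dict, ns, value) {
  which(dict$entries$namespace == ns & dict$entries$value == value)
}

dict_has_value <- function(dict, ns, value) length(dict_find(dict, ns, value)) > 0L

dict_entity_class <- function(dict, ns, value) {
  i <- dict_find(dict, ns, value)
  if (length(i) == 0L) return(NA_character_)
  dict$entries$entity_class[i[1L]]
}

# Synonym matching key: alphanumeric token runs joined by a single space.
# Synonyms whose alphanumeric content is <= 3 characters match
# case-sensitively (short gene symbols such as FAS vs Fas are distinct);
# longer synonyms match case-insensitively.
.match_tokens <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1L]]
  if (m[1L] == -1L) return(character(0))
  regmatches(text, list(m))[[1L]]
}

.synonym_key <- function(synonym) {
  toks <- .match_tokens(synonym)
  if (length(toks) == 0L) return(list(key = NA_character_, n = 0L, cs = FALSE))
  joined <- paste(toks, collapse = " ")
  cs <- nchar(gsub(" ", "", joined, fixed = TRUE)) <= 3L
  list(key = if (cs) joined else tolower(joined), n = length(toks), cs = cs)
}

#' Synonym index of a dictionary
#'
#' One row per (entry, synonym): the normalized match key, its token count,
#' whether matching is case-sensitive, and the concept columns. A
#' pre-computed index may be attached as attribute `"index"`.
#'
#' @param dict A `bel_dictionary`.
#' @return A data.frame.
#' @keywords internal
dict_index <- function(dict) {
  cached <- attr(dict, "index")
  if (!is.null(cached)) return(cached)
  e <- dict$entries
  if (nrow(e) == 0L)
    return(data.frame(key = character(0), n_tokens = integer(0),
                      case_sensitive = logical(0), namespace = character(0),
                      value = character(0), entity_class = character(0),
                      organism = character(0)))
  rows <- lapply(seq_len(nrow(e)), function(i) {
    syns <- e$synonyms[[i]]
    keys <- lapply(syns, .synonym_key)
    ok <- vapply(keys, function(k) k$n > 0L, logical(1))
    keys <- keys[ok]
    if (length(keys) == 0L) return(NULL)
    data.frame(key = vapply(keys, `[[`, "", "key"),
               n_tokens = vapply(keys, `[[`, 0L, "n"),
               case_sensitive = vapply(keys, `[[`, FALSE, "cs"),
               namespace = e$namespace[i], value = e$value[i],
               entity_class = e$entity_class[i], organism = e$organism[i],
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  idx[!duplicated(idx), , drop = FALSE]
}

#' Look up a surface string in a dictionary
#'
#' Applies the same normalization as the entity tagger (token runs, short
#' synonyms case-sensitive, long synonyms case-insensitive) and returns all
#' concepts whose synonym matches.
#'
#' @param dict A `bel_dictionary`.
#' @param surface The text to look up, e.g. `"early growth response-1"`.
#' @return A data.frame of candidate concepts (possibly zero rows) with
#'   columns `namespace`, `value`, `entity_class`, `organism`.
#' @export
dict_lookup <- function(dict, surface) {
  idx <- dict_index(dict)
  toks <- .match_tokens(surface)
  raw <- paste(toks, collapse = " ")
  hit <- (idx$case_sensitive & idx$key == raw) |
    (!idx$case_sensitive & idx$key == tolower(raw))
  out <- idx[hit, c("namespace", "value", "entity_class", "organism"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge dictionaries
#'
#' @param ... `bel_dictionary` objects.
#' @return A single `bel_dictionary` with synonym lists unioned on duplicate
#'   concepts.
#' @export
merge_dictionaries <- function(...) {
  dicts <- list(...)
  entries <- do.call(rbind, lapply(dicts, function(d) {
    e <- d$entries
    e$synonyms <- lapply(seq_len(nrow(e)), function(i) e$synonyms[[i]])
    e
  }))
  bel_dictionary(entries)
}
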