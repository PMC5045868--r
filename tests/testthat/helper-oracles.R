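# Independent oracles used across the test files.

# Exhaustive one-to-one matcher: maximal number of predicted components that
# can be paired with distinct gold components under `match_fn`. Used to
# check the greedy scorer; feasible for the <= 6 statements per sentence the
# fixtures use.
exhaustive_tp <- function(pred, gold, match_fn) {
  n_pred <- length(pred)
  if (n_pred == 0L) return(0L)
  best <- 0L
  recurse <- function(i, used, tp) {
    if (tp + (n_pred - i + 1L) <= best) return()
    if (i > n_pred) {
      best <<- max(best, tp)
      return()
    }
    recurse(i + 1L, used, tp)  # leave pred i unmatched
    for (j in seq_along(gold)) {
      if (used[j]) next
      if (match_fn(pred[[i]], gold[[j]])) {
        used[j] <- TRUE
        recurse(i + 1L, used, tp + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(gold)), 0L)
  best
}

# Triple records as plain lists for the oracle.
oracle_triples <- function(statements) {
  tri <- do.call(rbind, lapply(statements,
                               function(s) decompose_statement(s)$R))
  tri <- unique(tri)
  lapply(seq_len(nrow(tri)), function(i) as.list(tri[i, ]))
}

oracle_exact <- function(p, g) {
  p$subject == g$subject && p$predicate == g$predicate &&
    p$object == g$object
}

oracle_rs <- function(p, g) {
  if (oracle_exact(p, g)) return(TRUE)
  subj <- !p$subject_placeholder && !g$subject_placeholder &&
    p$subject == g$subject
  pred <- p$predicate == g$predicate
  obj <- p$object == g$object
  (subj && pred) || (pred && obj) || (subj && obj)
}

# Exhaustive TP at a triple level for one sentence.
oracle_level_tp <- function(gold, pred, level) {
  match_fn <- if (level == "R") oracle_exact else oracle_rs
  exhaustive_tp(oracle_triples(pred), oracle_triples(gold), match_fn)
}

# All permutations of seq_len(n) (n <= 4 in the tests that use this).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

fixture_vocab <- fixture_dictionaries()
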