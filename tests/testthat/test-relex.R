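# Event model, standoff input/output, baseline extractors.

random_event_set <- function(n, seed) {
  withr::with_seed(seed, {
    mention_ids <- paste0("T", 1:6)
    events <- list()
    for (i in seq_len(n)) {
      type <- sample(EVENT_TYPES, 1L)
      trigger <- list(start = (i - 1L) * 10L, end = (i - 1L) * 10L + 5L,
                      text = paste0("trig", i))
      theme <- sample(mention_ids, 1L)
      theme2 <- if (type == "Binding" && runif(1) < 0.5)
        sample(setdiff(mention_ids, theme), 1L)
      cause <- if (type %in% REGULATION_TYPES && runif(1) < 0.6)
        sample(setdiff(mention_ids, theme), 1L)
      site <- if (type == "Phosphorylation" && runif(1) < 0.5)
        list(start = 100L + i, end = 107L + i, text = "Thr-426")
      events[[i]] <- bel_event(paste0("E", i), type, trigger, theme,
                               theme2 = theme2, cause = cause, site = site)
    }
    events
  })
}

test_mentions <- data.frame(
  id = paste0("T", 1:6),
  start = seq(0L, 50L, by = 10L), end = seq(4L, 54L, by = 10L),
  surface = c("AHR", "FAS", "JUN", "HGF", "STAT4", "IL10"),
  class = "gene_protein", stringsAsFactors = FALSE)

test_that("event invariants are enforced at construction", {
  trig <- list(start = 0L, end = 4L, text = "decr")
  expect_error(bel_event("E1", "Sumoylation", trig, "T1"), "unknown event")
  expect_error(bel_event("E1", "Gene_expression", trig, NULL), "Theme")
  expect_error(bel_event("E1", "Gene_expression", trig, "T1", theme2 = "T2"),
               "Binding")
  expect_error(bel_event("E1", "Binding", trig, "T1", cause = "T2"),
               "regulation")
})

test_that("standoff files round-trip mentions and events", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("d.txt", "d.a1", "d.a2"))
  text <- paste(rep("Galangin induced AhR nuclear translocation.", 2),
                collapse = " ")
  for (n in c(0L, 5L, 20L)) {
    events <- random_event_set(n, seed = 100 + n)
    write_standoff(test_mentions, events, text, paths[1], paths[2], paths[3])
    back <- read_standoff(paths[1], paths[2], paths[3])
    expect_equal(back$mentions[, c("id", "start", "end", "surface", "class")],
                 test_mentions, ignore_attr = TRUE)
    expect_length(back$events, n)
    for (i in seq_len(n)) {
      got <- back$events[[i]]
      want <- events[[i]]
      for (f in c("id", "type", "theme", "theme2", "cause", "trigger",
                  "site"))
        expect_equal(got[[f]], want[[f]], info = paste(n, i, f))
    }
  }
})

test_that("standoff reader rejects dangling references", {
  dir <- withr::local_tempdir()
  writeLines("NF-AT interacts with Foxp3.", file.path(dir, "d.txt"))
  writeLines("T1\tgene_protein 0 5\tNF-AT", file.path(dir, "d.a1"))
  writeLines(c("T9\tBinding 6 15\tinteracts",
               "E1\tBinding:T9 Theme:T5"), file.path(dir, "d.a2"))
  expect_error(read_standoff(file.path(dir, "d.txt"), file.path(dir, "d.a1"),
                             file.path(dir, "d.a2")),
               "unknown annotation T5")
  # empty a2 -> zero events
  writeLines(character(0), file.path(dir, "d.a2"))
  r <- read_standoff(file.path(dir, "d.txt"), file.path(dir, "d.a1"),
                     file.path(dir, "d.a2"))
  expect_length(r$events, 0L)
})

sentence_setup <- function(text) {
  m <- harmonize_mentions(annotate_mentions(text, fixture_vocab), text)
  sentence_mentions(m, split_sentences(text)[1, ])
}

test_that("trigger-lexicon extraction recovers the regulation cascade", {
  text <- "Galangin induced AhR nuclear translocation."
  sm <- sentence_setup(text)
  events <- extract_events(text, sm)
  types <- vapply(events, `[[`, "", "type")
  expect_setequal(types, c("Localization", "PositiveRegulation"))
  loc <- events[[which(types == "Localization")]]
  reg <- events[[which(types == "PositiveRegulation")]]
  ahr <- sm$id[sm$surface == "AhR"]
  gal <- sm$id[sm$surface == "Galangin"]
  expect_equal(loc$theme, ahr)
  expect_equal(loc$to_loc$text, "nuclear")
  expect_equal(reg$theme, loc$id)
  expect_equal(reg$cause, gal)
})

test_that("binding and bare-sentence extraction behave", {
  text <- "NF-AT interacts with Foxp3."
  sm <- sentence_setup(text)
  events <- extract_events(text, sm)
  expect_length(events, 1L)
  expect_equal(events[[1]]$type, "Binding")
  expect_equal(events[[1]]$theme, sm$id[sm$surface == "NF-AT"])
  expect_equal(events[[1]]$theme2, sm$id[sm$surface == "Foxp3"])

  # mentions but no trigger word
  text2 <- "STAT4 and Interleukin 10 were measured."
  expect_length(extract_events(text2, sentence_setup(text2)), 0L)
  # trigger but no mention
  expect_length(extract_events("Expression was measured.",
                               sentence_setup("Expression was measured.")),
                0L)
})

test_that("phosphorylation sites and regulation of events are attached", {
  text <- "Phosphorylation of Thr-426 in SREBP1a"
  sm <- sentence_setup(text)
  events <- extract_events(text, sm)
  expect_length(events, 1L)
  expect_equal(events[[1]]$type, "Phosphorylation")
  expect_equal(events[[1]]$site$text, "Thr-426")

  text2 <- "GRK2 decreases early growth response-1 expression."
  sm2 <- sentence_setup(text2)
  events2 <- extract_events(text2, sm2)
  types <- vapply(events2, `[[`, "", "type")
  expect_setequal(types, c("Gene_expression", "NegativeRegulation"))
  reg <- events2[[which(types == "NegativeRegulation")]]
  expect_equal(reg$theme, events2[[which(types == "Gene_expression")]]$id)
  expect_equal(reg$cause, sm2$id[sm2$surface == "GRK2"])
})

test_that("association pairs follow cue words and text order", {
  text <- "STAT4 controls Interleukin 10."
  sm <- sentence_setup(text)
  pairs <- extract_associations(text, sm)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$entity1, sm$id[sm$surface == "STAT4"])
  expect_equal(pairs$entity2, sm$id[sm$surface == "Interleukin 10"])
  expect_equal(pairs$score, 1)

  # a single mention can never pair
  text2 <- "STAT4 controls everything."
  expect_equal(nrow(extract_associations(text2, sentence_setup(text2))), 0L)

  # no cue word: nothing unless all_pairs is on
  text3 <- "STAT4, Interleukin 10 and JUN were measured in livers."
  sm3 <- sentence_setup(text3)
  expect_equal(nrow(extract_associations(text3, sm3)), 0L)
  all3 <- extract_associations(text3, sm3,
                               association_config(all_pairs = TRUE))
  n <- sum(sm3$selected_class %in% c("gene_protein", "family", "complex",
                                     "chemical", "bioprocess"))
  expect_equal(nrow(all3), n * (n - 1) / 2)
})

test_that("extraction is deterministic for fixed inputs", {
  text <- "Galangin induced AhR nuclear translocation."
  sm <- sentence_setup(text)
  expect_identical(extract_events(text, sm), extract_events(text, sm))
  expect_identical(extract_associations(text, sm),
                   extract_associations(text, sm))
})
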