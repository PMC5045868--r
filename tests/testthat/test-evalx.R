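# Multi-level scoring.

eval_tables <- function() {
  ex <- demo_eval_corpus()
  list(
    gold = do.call(rbind, lapply(ex, function(e)
      data.frame(sentence_id = e$sentence_id, statement = e$gold,
                 stringsAsFactors = FALSE))),
    pred = do.call(rbind, lapply(ex, function(e)
      data.frame(sentence_id = e$sentence_id, statement = e$predicted,
                 stringsAsFactors = FALSE))))
}

test_that("decomposition extracts entities, functions and triples", {
  d <- decompose_statement("a(CHEBI:galangin) -> act(p(HGNC:AHR))")
  expect_setequal(d$T, c("CHEBI:galangin", "HGNC:AHR"))
  expect_equal(d$FS, "act")
  expect_equal(d$F, "act|HGNC:AHR")
  expect_equal(nrow(d$R), 1L)
  expect_equal(unlist(d$R[1, 1:3], use.names = FALSE),
               c("CHEBI:galangin", "->", "HGNC:AHR"))

  # the placeholder is not a normalized entity
  d2 <- decompose_statement(
    'p(PH:placeholder) -| (p(HGNC:FAS) -> bp(GOBP:"cell death"))')
  expect_setequal(d2$T, c("HGNC:FAS", "GOBP:cell death"))
  expect_equal(nrow(d2$R), 2L)
  expect_true(any(d2$R$subject_placeholder))

  # a bare two-entity association has no function components
  d3 <- decompose_statement("p(HGNC:STAT4) -- p(HGNC:IL10)")
  expect_length(d3$FS, 0L)
  expect_length(d3$F, 0L)

  # complexes count as function components, one per member
  d4 <- decompose_statement(
    "complex(p(HGNC:NFAT1),p(HGNC:FOXP3)) -> bp(GOBP:\"cell death\")")
  expect_setequal(d4$F, c("complex|HGNC:NFAT1", "complex|HGNC:FOXP3"))
  # pmod attaches to its carrying protein
  d5 <- decompose_statement(
    'bp(GOBP:"response to ionizing radiation") -> p(HGNC:JUN,pmod(P))')
  expect_equal(d5$F, "pmod|HGNC:JUN")
})

test_that("worked examples score as printed at statement level", {
  ex <- demo_eval_corpus()
  # one exact hit plus one spurious pair
  expect_equal(match_statements(ex[[1]]$gold, ex[[1]]$predicted, "S"),
               c(tp = 1L, fp = 1L, fn = 1L))
  sc <- score_counts(1, 1, 1)
  expect_equal(unname(sc["precision"]), 0.5)
  expect_equal(unname(sc["recall"]), 0.5)
  # function-level mismatch still scores at relationship level
  expect_equal(match_statements(ex[[2]]$gold, ex[[2]]$predicted, "R"),
               c(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(match_statements(ex[[2]]$gold, ex[[2]]$predicted, "S"),
               c(tp = 0L, fp = 1L, fn = 1L))
  expect_equal(match_statements(ex[[2]]$gold, ex[[2]]$predicted, "F"),
               c(tp = 0L, fp = 1L, fn = 1L))
  # complete miss: three false positives at statement level
  expect_equal(match_statements(ex[[3]]$gold, ex[[3]]$predicted, "S"),
               c(tp = 0L, fp = 3L, fn = 2L))
  # partial credit for the nested gold statement
  rs <- match_statements(ex[[4]]$gold, ex[[4]]$predicted, "RS")
  expect_equal(unname(rs["tp"]), 2L)
  expect_equal(unname(rs["fn"]), 0L)
})

test_that("statement classification distinguishes exact and partial hits", {
  ex <- demo_eval_corpus()
  expect_equal(classify_predictions(ex[[1]]$gold, ex[[1]]$predicted),
               c("TP", "FP"))
  expect_equal(classify_predictions(ex[[4]]$gold, ex[[4]]$predicted)[1:2],
               c("partial", "partial"))
})

test_that("score formulas match direct evaluation on random counts", {
  withr::with_seed(17, {
    for (i in 1:50) {
      tp <- sample(0:20, 1)
      fp <- sample(0:20, 1)
      fn <- sample(0:20, 1)
      got <- score_counts(tp, fp, fn)
      p <- if (tp + fp == 0) 1 else tp / (tp + fp)
      r <- if (tp + fn == 0) 1 else tp / (tp + fn)
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      expect_equal(unname(got), c(p, r, f))
    }
  })
  expect_equal(unname(score_counts(0, 0, 5)),
               c(1, 0, 0))  # empty predictions: full precision, no recall
})

test_that("identical corpora score perfectly; disjoint ids count FP/FN", {
  tabs <- eval_tables()
  perfect <- evaluate_statements(tabs$gold, tabs$gold)
  expect_true(all(perfect$precision == 100))
  expect_true(all(perfect$recall == 100))
  # a sentence present only in gold contributes FN, only in pred FP
  g <- data.frame(sentence_id = c("a", "b"),
                  statement = c("p(HGNC:FAS) -> p(HGNC:JUN)",
                                "p(HGNC:HGF) -| p(HGNC:FAS)"))
  p <- data.frame(sentence_id = c("a", "c"),
                  statement = c("p(HGNC:FAS) -> p(HGNC:JUN)",
                                "p(HGNC:STAT4) -- p(HGNC:IL10)"))
  rep <- evaluate_statements(g, p)
  s <- rep[rep$level == "S", ]
  expect_equal(c(s$TP, s$FP, s$FN), c(1L, 1L, 1L))
  expect_error(evaluate_statements(
    data.frame(sentence_id = "x", statement = "p(HGNC:FAS"),
    data.frame(sentence_id = "x", statement = "p(HGNC:FAS) -> p(HGNC:JUN)")),
    "sentence x")
})

test_that("swapping gold and predicted swaps precision and recall", {
  tabs <- eval_tables()
  fwd <- evaluate_statements(tabs$gold, tabs$pred)
  rev <- evaluate_statements(tabs$pred, tabs$gold)
  expect_equal(fwd$precision, rev$recall)
  expect_equal(fwd$recall, rev$precision)
})

test_that("adding a correct prediction never lowers recall at any level", {
  tabs <- eval_tables()
  base <- evaluate_statements(tabs$gold, tabs$pred)
  for (k in seq_len(nrow(tabs$gold))) {
    extra <- rbind(tabs$pred, tabs$gold[k, ])
    grown <- evaluate_statements(tabs$gold, extra)
    expect_true(all(grown$recall >= base$recall), info = k)
  }
})

test_that("greedy matching agrees with the exhaustive oracle", {
  ex <- demo_eval_corpus()
  for (e in ex) {
    for (level in c("R", "RS")) {
      greedy <- match_statements(e$gold, e$predicted, level)
      expect_equal(unname(greedy["tp"]),
                   oracle_level_tp(e$gold, e$predicted, level),
                   info = paste(e$sentence_id, level))
    }
  }
  # and on generated statement sets with perturbations
  withr::with_seed(23, {
    pool <- generate_statements(40, seed = 23)
    for (rep in 1:10) {
      gold <- sample(pool, sample(2:5, 1))
      pred <- c(sample(gold, sample(1:2, 1)), sample(pool, sample(1:3, 1)))
      for (level in c("R", "RS")) {
        greedy <- match_statements(gold, pred, level)
        expect_equal(unname(greedy["tp"]), oracle_level_tp(gold, pred, level))
      }
    }
  })
})

test_that("coarser relationship levels match at least as much as finer", {
  tabs <- eval_tables()
  corpora <- list(tabs,
                  list(gold = tabs$gold, pred = tabs$gold),
                  list(gold = tabs$gold,
                       pred = tabs$pred[seq(1, nrow(tabs$pred), 2), ]))
  for (co in corpora) {
    rep <- evaluate_statements(co$gold, co$pred)
    tp <- setNames(rep$TP, rep$level)
    expect_lte(tp[["S"]], tp[["R"]])
    expect_lte(tp[["R"]], tp[["RS"]])
  }
})
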