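# Pipeline orchestration, BELScript export/import, validity statistics, CLI.

test_that("the pipeline proposes statements with evidence and context", {
  doc <- run_pipeline("NF-AT interacts with Foxp3.", fixture_vocab)
  expect_equal(doc$status, "processed")
  expect_equal(doc$statements$statement,
               "p(HGNC:NFAT1) -- p(HGNC:FOXP3)")
  expect_equal(doc$statements$origin, "association")

  # binding alone yields no statement when associations are off
  doc_noassoc <- run_pipeline("NF-AT interacts with Foxp3.", fixture_vocab,
                              pipeline_config(associations = FALSE))
  expect_equal(nrow(doc_noassoc$statements), 0L)

  doc2 <- run_pipeline("Galangin induced AhR nuclear translocation.",
                       fixture_vocab)
  expect_true("a(CHEBI:galangin) -> tloc(p(HGNC:AHR),GOCC:Nucleus)" %in%
                doc2$statements$statement)

  # document-scope context annotations are attached to each statement
  doc3 <- run_pipeline(
    "SIRT1 decreases early growth response-1 expression in mouse livers.",
    fixture_vocab)
  expect_gt(nrow(doc3$statements), 0L)
  annos <- doc3$statements$annotations[[1]]
  expect_true(any(vapply(annos, function(a) a$class == "MESHAnatomy",
                         TRUE)))

  # empty and mention-free documents process cleanly with zero statements
  empty <- run_pipeline("", fixture_vocab)
  expect_equal(empty$status, "processed")
  expect_equal(nrow(empty$statements), 0L)
  bare <- run_pipeline("Expression increased dramatically.", fixture_vocab)
  expect_equal(nrow(bare$statements), 0L)
})

test_that("pipeline output is deterministic", {
  text <- "Galangin induced AhR nuclear translocation in mouse livers."
  a <- run_pipeline(text, fixture_vocab)
  b <- run_pipeline(text, fixture_vocab)
  expect_identical(a$statements, b$statements)
})

export_ready_doc <- function(text = "Galangin induced AhR nuclear translocation.") {
  doc <- run_pipeline(text, fixture_vocab)
  doc$statements$export <- TRUE
  doc$citation <- utils::modifyList(
    doc$citation, list(journal = "J Cell Biol", pmid = "12345678"))
  doc
}

test_that("exported BELScript re-reads identically and re-validates clean", {
  doc <- export_ready_doc()
  text <- write_belscript(doc, fixture_vocab)
  expect_match(text, "DEFINE NAMESPACE HGNC AS URL")
  expect_match(text, "SET Citation = \\{\"PubMed\",\"J Cell Biol\",\"12345678\"\\}")
  expect_match(text, "increases")  # keyword dialect
  back <- read_belscript(text)
  expect_setequal(back$statements$statement, doc$statements$statement)
  expect_equal(unique(back$statements$evidence),
               unique(doc$statements$evidence))
  expect_equal(back$citation$pmid, "12345678")
  # export gating soundness: nothing invalid survives a round trip
  expect_true(all(vapply(back$statements$statement, bel_is_valid, TRUE,
                         vocab = fixture_vocab)))
  expect_true(all(is.na(back$statements$diagnostic)))
})

test_that("export is refused for placeholders, errors or missing citation", {
  # placeholder subject
  doc <- run_pipeline("SIRT1 is reduced in mouse livers.", fixture_vocab)
  expect_true(any(grepl("PH:placeholder", doc$statements$statement)))
  doc$statements$export <- TRUE
  doc$citation$pmid <- "7"
  expect_error(write_belscript(doc, fixture_vocab),
               class = "belscript_export_refused")

  # missing citation
  doc2 <- export_ready_doc()
  doc2$citation$pmid <- NULL
  expect_error(write_belscript(doc2, fixture_vocab),
               class = "belscript_export_refused")

  # invalid statement among the flagged ones blocks the whole document
  doc3 <- export_ready_doc()
  doc3$statements <- rbind(doc3$statements,
                           data.frame(statement = "a(QQX:thing) -> p(HGNC:FUS)",
                                      evidence = "bad", export = TRUE,
                                      origin = "manual",
                                      annotations = I(list(list()))))
  err <- tryCatch(write_belscript(doc3, fixture_vocab),
                  belscript_export_refused = identity)
  expect_s3_class(err, "belscript_export_refused")
  expect_true(any(grepl("QQX", err$offending)))

  # no flagged statements: header-only script plus a warning
  doc4 <- export_ready_doc()
  doc4$statements$export <- FALSE
  expect_warning(text <- write_belscript(doc4, fixture_vocab),
                 "no statements flagged")
  expect_match(text, "DEFINE")
})

test_that("imported documents keep malformed statement lines with diagnostics", {
  doc <- export_ready_doc()
  lines <- strsplit(write_belscript(doc, fixture_vocab), "\n")[[1]]
  broken <- sub("^a\\(CHEBI:galangin\\) increases .*$",
                "a(CHEBI:galangin increases", lines)
  back <- read_belscript(paste(broken, collapse = "\n"))
  bad <- !is.na(back$statements$diagnostic)
  expect_equal(sum(bad), 1L)
  expect_match(back$statements$diagnostic[bad], "unbalanced|predicate")
  # unknown SET keys are kept as opaque annotations
  with_extra <- c(lines[1:3], "SET Species = \"9606\"", lines[-(1:3)])
  back2 <- read_belscript(paste(with_extra, collapse = "\n"))
  annos <- unlist(lapply(back2$statements$annotations, function(a)
    vapply(a, `[[`, "", "class")))
  expect_true("Species" %in% annos)
})

test_that("validity statistics reproduce planted rates and ignore order", {
  corpus <- generate_corpus(corpus_spec(6, 30, 5, 2), seed = 42)
  st <- curation_stats(corpus, fixture_vocab)
  expect_equal(st$n_statements, 30L)
  expect_equal(st$n_invalid_statements, 5L)
  expect_equal(st$invalid_statement_rate, round(100 * 5 / 30, 2))
  expect_equal(st$n_invalid_documents, 2L)
  expect_equal(st$invalid_document_rate, round(100 * 2 / 6, 1))
  expect_equal(st$n_valid_statements + st$n_invalid_statements,
               st$n_statements)

  # permutation invariance over document order
  shuffled <- corpus
  ord <- rev(seq_len(nrow(shuffled$statements)))
  shuffled$statements <- shuffled$statements[ord, ]
  st2 <- curation_stats(shuffled, fixture_vocab)
  expect_equal(unclass(st)[], unclass(st2)[])

  # all-valid corpus has zero rates
  clean <- curation_stats(generate_corpus(corpus_spec(2, 4), seed = 1),
                          fixture_vocab)
  expect_equal(clean$invalid_statement_rate, 0)
  expect_equal(clean$invalid_document_rate, 0)
})

test_that("stats also run over exported BELScript files", {
  dir <- withr::local_tempdir()
  doc <- export_ready_doc()
  writeLines(write_belscript(doc, fixture_vocab),
             file.path(dir, "doc1.bel"))
  st <- curation_stats(file.path(dir, "doc1.bel"), fixture_vocab)
  expect_equal(st$n_documents, 1L)
  expect_equal(st$n_invalid_statements, 0L)
})

test_that("the CLI wires commands to exit statuses", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "corpus")
  expect_equal(bel_cli(c("fixtures", "--docs", "3", "--statements", "9",
                         "--seed", "5", "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "gold_statements.tsv")))

  gold <- file.path(out, "gold_statements.tsv")
  rep_json <- file.path(dir, "report.json")
  expect_equal(suppressMessages(
    bel_cli(c("score", "--gold", gold, "--pred", gold,
              "--out", rep_json))), 0L)
  rep <- jsonlite::read_json(rep_json, simplifyVector = TRUE)
  expect_true(all(rep$precision == 100))

  # export of a statement table with placeholders is refused (status 1)
  tsv <- file.path(dir, "bad.tsv")
  writeLines(c("sentence_id\tstatement",
               "s1\ta(PH:placeholder) -| p(HGNC:FAS)"), tsv)
  cite <- file.path(dir, "cite.json")
  writeLines('{"journal":"J","pmid":"1"}', cite)
  expect_equal(suppressMessages(
    bel_cli(c("export", "--statements", tsv, "--citation", cite,
              "--out", file.path(dir, "out.bel")))), 1L)

  # valid table exports and stats read it back
  tsv2 <- file.path(dir, "good.tsv")
  writeLines(c("sentence_id\tstatement",
               "s1\tp(HGNC:STAT4) -- p(HGNC:IL10)"), tsv2)
  expect_equal(suppressMessages(
    bel_cli(c("export", "--statements", tsv2, "--citation", cite,
              "--out", file.path(dir, "good.bel")))), 0L)
  expect_equal(suppressMessages(
    bel_cli(c("stats", "--bel", file.path(dir, "good.bel"),
              "--out", file.path(dir, "stats.json")))), 0L)
  st <- jsonlite::read_json(file.path(dir, "stats.json"))
  expect_equal(st$n_invalid_statements, 0L)

  expect_equal(bel_cli(c("nosuchcommand")), 2L)
  expect_equal(suppressMessages(bel_cli(c("score", "--gold", gold))), 2L)
})
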