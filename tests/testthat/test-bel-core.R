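# Parser, canonical form, serializer and validator.

test_that("statements parse into subject/predicate/object structure", {
  s <- parse_bel_statement(
    'a(CHEBI:corticosteroid) -| bp(MESHPP:"Oxidative Stress")')
  expect_s3_class(s, "bel_statement")
  expect_equal(s$relation, "-|")
  expect_equal(s$subject$fn, "a")
  expect_equal(s$subject$ns, "CHEBI")
  expect_equal(s$object$fn, "bp")
  expect_equal(s$object$value, "Oxidative Stress")

  nested <- parse_bel_statement(
    'p(HGNC:HGF) -| (act(p(HGNC:FAS)) -> bp(GOBP:"cell death"))')
  expect_s3_class(nested$object, "bel_statement")
  expect_equal(nested$object$relation, "->")
  expect_equal(nested$object$subject$fn, "act")

  # keyword predicates and typographic glyphs normalize to the same form
  expect_equal(bel_canonical_text("p(HGNC:STAT4) association p(HGNC:IL10)"),
               "p(HGNC:STAT4) -- p(HGNC:IL10)")
  expect_equal(bel_canonical_text("p(HGNC:STAT4) −− p(HGNC:IL10)"),
               "p(HGNC:STAT4) -- p(HGNC:IL10)")
})

test_that("terms parse with pmod, tloc and complex structure", {
  t <- parse_bel_term("p(HGNC:SREBF1, pmod(P,T,426))")
  expect_length(t$pmods, 1L)
  expect_equal(t$pmods[[1]]$type, "P")
  expect_equal(t$pmods[[1]]$residue, "T")
  expect_equal(t$pmods[[1]]$position, 426L)

  tl <- parse_bel_term("tloc(p(HGNC:AHR),GOCC:Nucleus)")
  expect_equal(tl$fn, "tloc")
  expect_equal(tl$args[[1]]$value, "AHR")
  expect_equal(tl$loc$ns, "GOCC")

  # a translocation without a known target location still parses
  expect_null(parse_bel_term("tloc(p(HGNC:AHR))")$loc)

  cx <- parse_bel_term('complex(SCOMP:"AP-1 Complex")')
  expect_equal(cx$fn, "complex")
  expect_equal(cx$ns, "SCOMP")

  bare <- parse_bel_term("p(HGNC:JUN,pmod(P))")
  expect_true(is.na(bare$pmods[[1]]$residue))
})

test_that("syntax errors carry position and a distinct bare-term message", {
  err <- tryCatch(parse_bel_statement("p(HGNC:EGR1)"),
                  bel_syntax_error = identity)
  expect_match(conditionMessage(err), "missing predicate")
  expect_equal(err$pos, 13L)

  expect_error(parse_bel_term("complex()"), "at least one entity",
               class = "bel_syntax_error")
  expect_error(parse_bel_statement("p(HGNC:EGR1 -> p(HGNC:FUS)"),
               "unbalanced", class = "bel_syntax_error")
  expect_error(parse_bel_term("q(HGNC:EGR1)"), "unknown function",
               class = "bel_syntax_error")
  expect_error(parse_bel_term("p(HGNC:EGR1,)"), "dangling comma",
               class = "bel_syntax_error")
  expect_error(parse_bel_term("a(CHEBI:galangin, pmod(P))"),
               "pmod outside protein/RNA term", class = "bel_syntax_error")
  expect_error(parse_bel_statement("p(HGNC:EGR1) ->"), "missing object",
               class = "bel_syntax_error")
})

test_that("canonicalization is idempotent, sorts complexes, trims quotes", {
  a <- bel_canonical_text("complex(p(HGNC:NFAT1), p(HGNC:FOXP3))")
  b <- bel_canonical_text("complex(p(HGNC:FOXP3), p(HGNC:NFAT1))")
  expect_identical(a, b)
  expect_identical(bel_canonical_text('a(CHEBI:"galangin")'),
                   "a(CHEBI:galangin)")
  expect_identical(bel_canonical_text('a(CHEBI:"cell death")'),
                   'a(CHEBI:"cell death")')
  # idempotence on a batch of generated statements
  for (s in generate_statements(40, seed = 11))
    expect_identical(bel_canonical_text(s), s)
})

test_that("canonical form of a complex is invariant under argument order", {
  members <- c("p(HGNC:FAS)", "a(CHEBI:galangin)", 'p(HGNC:JUN,pmod(P))',
               "bp(GOBP:\"cell death\")")
  for (n in 2:4) {
    reference <- NULL
    for (perm in all_permutations(n)) {
      text <- paste0("complex(", paste(members[perm], collapse = ","), ")")
      canon <- bel_canonical_text(text)
      if (is.null(reference)) reference <- canon
      expect_identical(canon, reference)
    }
  }
})

test_that("serialization round-trips parsed statements", {
  fixed <- c(
    'a(CHEBI:corticosteroid) -| bp(MESHPP:"Oxidative Stress")',
    'p(HGNC:HGF) -| (act(p(HGNC:FAS)) -> bp(GOBP:"cell death"))',
    'p(PH:placeholder) -| (a(CHEBI:"cadmium dichloride") -> p(HGNC:JUN,pmod(P)))')
  for (text in fixed) {
    canon <- bel_canonical_text(text)
    expect_identical(bel_text(parse_bel_statement(canon)), canon)
  }
  # keyword dialect re-parses to the same structure
  s <- parse_bel_statement(fixed[2])
  kw <- bel_serialize(bel_canonical(s), dialect = "keyword")
  expect_match(kw, "increases")
  expect_identical(bel_canonical_text(kw), bel_canonical_text(fixed[2]))
})

test_that("round-trip identity holds on generated statements", {
  for (s in generate_statements(200, seed = 3)) {
    expect_identical(bel_text(parse_bel_statement(s)), s)
  }
})

test_that("validator accepts fixture statements and flags known defects", {
  ok <- bel_validate(
    parse_bel_statement('a(CHEBI:"N-acetyl-D-galactosamine") -| p(HGNC:FUS)'),
    fixture_vocab)
  expect_equal(nrow(ok), 0L)

  d <- bel_validate_text(
    'p(PH:placeholder) -| (p(HGNC:FAS) -> bp(GOBP:"cell death"))',
    fixture_vocab)
  expect_equal(d$code, "PLACEHOLDER")
  expect_equal(d$severity, "warning")

  d <- bel_validate_text("a(HGNC:NOSUCHGENE) -> p(HGNC:FUS)", fixture_vocab)
  expect_equal(d$code, "UNKNOWN_VALUE")
  expect_match(d$message, "unknown value in namespace HGNC")

  d <- bel_validate_text("a(QQX:thing) -> p(HGNC:FUS)", fixture_vocab)
  expect_equal(d$code, "UNKNOWN_NAMESPACE")

  # protein abundance over a chemical concept is a class mismatch
  d <- bel_validate_text("p(CHEBI:galangin) -> p(HGNC:JUN)", fixture_vocab)
  expect_equal(d$code, "FUNCTION_CLASS_MISMATCH")

  # disease concepts are excluded from statements unless enabled
  d <- bel_validate_text("a(MESHD:Atherosclerosis) -> p(HGNC:JUN)",
                         fixture_vocab)
  expect_equal(d$code, "CONTEXT_CLASS")
  d2 <- bel_validate_text("a(MESHD:Atherosclerosis) -> p(HGNC:JUN)",
                          fixture_vocab,
                          bel_validate_config(allow_disease = TRUE))
  expect_equal(nrow(d2), 0L)

  # parse failures become SYNTAX diagnostics with an offset
  d <- bel_validate_text("p(HGNC:EGR1 -> p(HGNC:FUS)", fixture_vocab)
  expect_equal(d$code, "SYNTAX")
  expect_false(is.na(d$start))
})

test_that("statements labeled valid re-parse without error", {
  for (s in generate_statements(60, seed = 5)) {
    expect_true(bel_is_valid(s, fixture_vocab))
    expect_silent(parse_bel_statement(s))
  }
})

test_that("diagnostics export as JSON records", {
  d <- bel_validate_text("a(QQX:thing) -> p(HGNC:FUS)", fixture_vocab)
  j <- jsonlite::fromJSON(diagnostics_json(d))
  expect_equal(j$code, "UNKNOWN_NAMESPACE")
  expect_true(all(c("severity", "message", "start") %in% names(j)))
})
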