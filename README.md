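# belminer

Turning biomedical text into Biological Expression Language (BEL)
statements — and checking the result.

Curators who build BEL network models spend most of their time translating
sentences like *"Galangin induced AhR nuclear translocation"* into
machine-readable triples such as

```
a(CHEBI:galangin) -> tloc(p(HGNC:AHR),GOCC:Nucleus)
```

`belminer` is a desk-scale R toolkit for that workflow and for evaluating
it. It provides:

* **bel core** — a parser, canonicalizer, serializer and syntax/semantic
  validator for the BEL statement subset used in sentence-level curation
  (abundance functions `a/p/r/bp/complex`, wrappers
  `act/pmod/deg/sec/surf/tloc`, predicates `-> -| --`, object-side
  nesting, quoted values, typographic-glyph normalization).
* **vocab** — dictionary resources as a simple TSV format
  (namespace, value, entity class, organism, pipe-separated synonyms), a
  bundled fixture vocabulary, and a deterministic synthetic corpus /
  statement generator with plantable validation defects.
* **ner** — sentence splitting, longest-match dictionary tagging,
  harmonization of overlapping mentions with organism ranking
  (HGNC > MGI > RGD, switched by document-level organism cues), and
  mapping of anatomy / cell-line / cell-structure mentions to context
  annotations.
* **relex** — a BioNLP-ST event model with `.txt/.a1/.a2` standoff
  input/output, a baseline trigger-lexicon event extractor and a
  co-occurrence association extractor; externally produced standoff (e.g.
  from a trained event extraction system) plugs in directly.
* **belwriter** — the event-to-BEL conversion rules: expression vs
  transcription abundance selection, phosphorylation sites
  (`pmod(P,T,426)`), localization dispatch to `sec/surf/tloc`, binding to
  `complex()`, regulations to `->`/`-|`/`--` statements with recursive
  objects, and the `a(PH:placeholder)` subject when no cause is found.
* **evalx** — scoring of predicted vs gold statements at the six levels
  used in community evaluations of BEL extraction: Term, Function-Secondary,
  Function, Relationship-Secondary, Relationship and Statement, with
  optimal one-to-one per-sentence matching and micro-averaged
  precision/recall/F.
* **workbench** — a curation document model, pipeline orchestration,
  BELScript export gated on validation (placeholders, syntax/semantic
  errors or a missing citation refuse the whole document), BELScript
  re-import, validity statistics, and a command-line interface.

## Worked example

```r
library(belminer)

dict <- fixture_dictionaries()
doc <- run_pipeline("Galangin induced AhR nuclear translocation.", dict)
doc$statements[, c("statement", "origin")]
#>                                             statement      origin
#> 1 a(CHEBI:galangin) -> tloc(p(HGNC:AHR),GOCC:Nucleus)       event
#> 2                    a(CHEBI:galangin) -- p(HGNC:AHR) association
```

The event route recovered the full causal statement: the trigger
"translocation" produced a Localization event on AhR with target
`GOCC:Nucleus`, and "induced" wrapped it in a positive regulation with
galangin as cause. The association route proposed the undirected
co-occurrence pair, which a curator would discard as redundant — the
toolkit deliberately does not filter it.

Scoring predictions against a gold standard (here the bundled worked
examples, four sentences with gold and predicted statement sets):

```r
ex <- demo_eval_corpus()
gold <- do.call(rbind, lapply(ex, \(e)
  data.frame(sentence_id = e$sentence_id, statement = e$gold)))
pred <- do.call(rbind, lapply(ex, \(e)
  data.frame(sentence_id = e$sentence_id, statement = e$predicted)))
evaluate_statements(gold, pred)
#> Class                          TP   FP   FN  Precision   Recall  F-score
#> Term (T)                        9    1    1      90.00    90.00    90.00
#> Function-Secondary (FS)         1    1    2      50.00    33.33    40.00
#> Function (F)                    1    1    2      50.00    33.33    40.00
#> Relationship-Secondary (RS)     6    4    0      60.00   100.00    75.00
#> Relationship (R)                3    7    3      30.00    50.00    37.50
#> Statement (S)                   1    8    5      11.11    16.67    13.33
```

Read bottom-up: only one prediction is a fully correct statement (S), but
most entities are normalized correctly (T = 90%), and at the
partial-credit relationship level (RS) every gold relationship is at least
partially recovered — the typical profile of an extraction pipeline whose
partial proposals a curator then completes.

## Command line

A thin launcher is installed under `inst/scripts/belminer`:

```sh
belminer extract  --input docs/ --out predicted.tsv
belminer score    --gold gold.tsv --pred predicted.tsv --out report.json
belminer export   --statements curated.tsv --citation cite.json --out doc.bel
belminer stats    --dir exported/ --out stats.json
belminer fixtures --docs 24 --statements 186 --defects 27 --defect-docs 8 \
                  --seed 42 --out corpus/
```

Exit status is 0 on success, 1 when an export is refused by validation and
2 on usage errors.

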