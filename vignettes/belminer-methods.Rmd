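---
title: "From sentences to BEL statements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sentences to BEL statements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belminer)
```

## The problem

Causal and correlative findings in the biomedical literature — "galangin
induces AhR nuclear translocation", "GRK2 decreases EGR1 expression" — are
routinely collated into network models written in the Biological Expression
Language (BEL). A BEL statement is a subject–predicate–object triple over
namespace-qualified concepts:

```
a(CHEBI:corticosteroid) -| bp(MESHPP:"Oxidative Stress")
```

Abundance functions (`a()` generic/chemical, `p()` protein, `r()` RNA,
`bp()` biological process, `complex()`) declare each entity's physical
form; regulatory wrappers (`act()`, `pmod()`, `deg()`, `sec()`, `surf()`,
`tloc()`) express activity, modification, degradation and localization.
Predicates are `->` (increases), `-|` (decreases) and `--` (undirected
association). An object may itself be a parenthesized statement, which is
how "X reduces the induction of Z by Y" is written.

`belminer` is a desk-scale toolkit around this representation: a parser and
validator for the statement subset used in sentence-level curation,
dictionary-based entity recognition, a BioNLP-style event model with
baseline extractors, rule-based translation of events into BEL, six-level
scoring of predictions against a gold standard, and a curation document
model with gated BELScript export.

## Parsing and canonical form

The grammar covers the constructs that occur in sentence-level extraction:
entity terms with one `namespace:value`, `pmod(type[, residue, position])`
inside `p()`/`r()`, wrapper functions of arity one, `tloc(term[,
GOCC:location])`, `complex()` with either a named-complex concept or one or
more member terms, and statements with optional object-side nesting.
Nesting on the subject side is rejected: the curation examples the toolkit
is built around show nested statements exclusively in object position, and
allowing both sides would make the relationship-level decomposition
ambiguous.

Text from the literature arrives with typographic glyphs, so en-dashes,
minus signs and curly quotes are normalized to ASCII before lexing; both
symbolic (`->`) and keyword (`increases`) predicate spellings are accepted.
Two deliberate relaxations: `pmod()` may omit residue and position (sites
are often unknown), and `tloc()` may omit its location concept (predicted
translocations frequently lack a resolvable target; such statements must
still parse and score).

The canonical form used for equality, deduplication and scoring is: ASCII
predicates with single surrounding spaces; no whitespace inside argument
lists; values double-quoted exactly when they contain a character outside
`[A-Za-z0-9]`; `complex()` members sorted lexicographically by their
canonical text, since binding partners are unordered. Canonicalization is
idempotent, and `parse(serialize(x))` is the identity on canonical forms —
both properties are tested on generated statements.

## Validation

`bel_validate()` checks a parsed node against a namespace catalog and a
class-compatibility matrix: chemicals only under `a()`; genes/proteins and
families under `a()`/`p()`/`r()`; named complexes under `complex()`;
processes under `bp()`; cell structures only as `tloc()` targets. Unknown
namespaces and unknown values are errors; anatomy, cell-line and disease
concepts inside a statement are errors (they belong in context
annotations). Disease concepts can be re-admitted with
`bel_validate_config(allow_disease = TRUE)`; the default excludes them
because no worked example uses one inside a statement. The artificial
placeholder `PH:placeholder` — inserted as subject when no cause is found —
is a *warning*, not an error: the scorer tolerates it, the exporter refuses
it. Diagnostics are data, never thrown, so a curation interface can render
them.

## Entity recognition and harmonization

Tagging is dictionary-based. Synonyms are indexed as alphanumeric token
sequences; matching is leftmost-longest per namespace, and hits with
identical spans are merged into one mention carrying every candidate
concept. Two policies matter in practice:

* **Case.** Synonyms of three characters or fewer match case-sensitively
  (`FAS` vs `Fas` are distinct synonyms; `ahr` must not hit `AhR`); longer
  synonyms match case-insensitively ("Early growth response-1" equals
  "early growth response-1"). The threshold is a choice made once: short
  gene symbols are where dictionary NER false-positives concentrate.
* **Harmonization.** Mentions strictly contained in a longer mention are
  suppressed ("EGF" inside "EGF receptor"). For identical spans with gene
  candidates from several organisms, a document-scope organism cue
  (human/patient, mouse/mice/murine, rat) selects that organism's
  namespace; otherwise a static rank applies, HGNC over MGI over RGD, and
  CHEBI over CHEMBL over SCHEM for chemicals. Ties break by lexicographic
  value for determinism. Cue scope is the whole document rather than the
  sentence because organism context is typically established once per
  abstract. All candidates stay on the mention for display.

Mentions from the anatomy, cell-line and cell-structure namespaces become
document-scope context annotations; gene, chemical and process mentions
never do. GOCC concepts, although classed as cell structures, are not
context annotations — they serve as `tloc()` targets.

## Events and baselines

The event model is the BioNLP shared-task one: nine types
(`Gene_expression`, `Transcription`, `Phosphorylation`,
`ProteinCatabolism`, `Localization`, `Binding` and the three regulation
types), a trigger span, a mandatory Theme, `Theme2` only for Binding, and
`Cause` only for regulations, with events permitted as regulation Themes.
Standoff `.txt/.a1/.a2` files round-trip through `read_standoff()` /
`write_standoff()`, so output of an external trained event extractor can be
ingested in place of the built-in baseline.

The built-in extractor is deliberately simple and deterministic: a trigger
stem lexicon (e.g. `induc*` → PositiveRegulation, `translocat*` →
Localization), nearest-mention argument attachment by token distance,
regulation Themes preferring a sibling event when one exists, and the Cause
taken from the opposite side of the trigger. There is no dependency
parsing, no negation or speculation handling, and no learning; it exists so
the pipeline runs end to end and the translation rules can be exercised.
The association baseline emits all unordered pairs of eligible mentions
when an interaction cue is present (`all_pairs = TRUE` removes the cue
requirement), with score 1 and text order preserved — it carries no
direction, so either member may be the true subject.

## Translation rules

`event_to_bel()` implements the conversion table: expression and
transcription yield bare terms (`p()` for triggers stemming from "express",
`r()` otherwise); phosphorylation yields `pmod(P[, residue, position])`
with sites like "Thr-426" parsed through a three-to-one-letter residue map;
degradation wraps in `deg()`; localization dispatches on the trigger and
location argument (`secret*` → `sec()`, `express*` or a surface location →
`surf()`, otherwise `tloc()` with the location looked up in a word→GOCC
map — an unmapped location is an error listing the text, never a guess);
binding builds a `complex()`; the three regulation types become statements
with `->`/`-|`/`--`, the object recursing into the Theme. A regulation
without a Cause gets the placeholder subject `a(PH:placeholder)`. The
writer never introduces `act()`, although the parser, validator and scorer
all support it. Only regulations and association pairs yield statements —
bare terms are not statements — and only textually identical duplicates are
removed, mirroring a pipeline that lacks deeper redundancy filtering.

## Scoring

Statements are compared at six levels: full statement text (S), relationship
triples (R), relationship with partial credit (RS), function–entity pairs
(F), function names alone (FS), and normalized entities (T, excluding the
placeholder). Triples take the *head entity* of each side — wrappers
stripped, a nested object contributing its own triples plus its innermost
head to the enclosing triple. At RS a predicted triple is credited when
subject+predicate, predicate+object, or subject+object agree with a gold
triple, with placeholder subjects never satisfying a subject match.

Matching is per sentence and one-to-one: each predicted component consumes
at most one gold component. The assignment is computed as a maximum
bipartite matching (augmenting paths) rather than a first-come greedy
pass, because greedy matching is order-dependent and can under-credit —
consuming a gold triple with an exact match that another prediction also
needed. With an optimal assignment the scorer agrees with an exhaustive
enumeration oracle by construction, which the tests verify on all fixture
sentences. Counts are summed over sentences (micro-average); precision and
recall define `0/0` as 1, and per-sentence duplicate gold statements are
collapsed by default (both conventions are configuration-level choices the
track description leaves open). `classify_predictions()` applies the same
one-to-one discipline to per-statement labels (`TP` / `partial` / `FP`)
for curator display.

## Curation documents and export gating

`run_pipeline()` chains splitting, tagging, harmonization, context mapping,
extraction and translation into a `curation_document`; stage failures mark
the document `failed` rather than raising. BELScript export writes `DEFINE
NAMESPACE`/`DEFINE ANNOTATION` headers and one evidence block per flagged
statement (`SET Citation`, `SET Evidence`, context-annotation `SET`s, the
statement in keyword dialect, matching `UNSET`s). One block per statement
rather than per sentence keeps the mapping between statements and evidence
unambiguous on re-import. The gate is strict and document-level: any
flagged statement with a validation error or a placeholder, or a missing
PubMed id, refuses the whole document and lists the offenders — so an
exported document always re-reads with zero invalid statements, which is
property-tested. Citation retrieval is an injectable input (a JSON fixture
in the CLI), not a live PubMed call.

## The synthetic corpus generator

`generate_corpus()` defines the conditions under which the validity
bookkeeping is exercised: statements drawn over the fixture vocabulary
(mixed abundances, ~10% phosphorylations, ~6% translocations, ~6%
complexes, 15% nested objects; predicate mix 45/35/20 for
`->`/`-|`/`--`), one templated evidence sentence per statement, and a
defect plan that corrupts a chosen number of statements — each violating
exactly one rule among `UNKNOWN_NAMESPACE`, `UNKNOWN_VALUE`,
`MISSING_OBJECT`, `UNBALANCED_PARENS` — confined to a chosen number of
documents. Generation is fully determined by `(spec, seed)`. The
reference configuration used by the tests and the acceptance script is 24
documents, 186 statements and 27 defects in 8 documents, the scale of a
hand-curation comparison: 27/186 gives an invalid-statement rate of
14.52% and 8/24 an invalid-document rate of 33.3%, and the validator must
recover exactly those rates from the corrupted text alone.

What the generator does *not* emulate: real sentence syntax (templates are
subject–verb–object), ambiguous or overlapping entity names beyond what the
fixture dictionary contains, cross-sentence relations, negation, and
co-reference. Green tests therefore demonstrate the correctness of the
machinery — parsing, validation, bookkeeping, scoring — not extraction
quality on real abstracts.

## Numerical and design choices

* Offsets are 0-based half-open everywhere; the standoff files use the same
  convention, so no conversion occurs on write.
* Complex members sort by canonical text with radix (byte) ordering, making
  canonical forms locale-independent.
* Residue map ships Ser/Thr/Tyr/His; the location map ships
  nuclear/nucleus → `Nucleus` and membrane → `"plasma membrane"`. Both are
  plain named vectors users can extend through `bel_ruleset()`.
* Equal-distance argument attachment ties prefer the following mention for
  regulation Themes (objects tend to follow the verb) and the preceding
  mention otherwise.
* Problem sizes in the tests: 1000 statements for the round-trip law, 200
  for serializer properties, corpora of 6–24 documents for bookkeeping;
  these sizes make every property suite complete in seconds while covering
  all grammar branches.

## Limitations

The extractor baselines are token-distance heuristics; on real text they
will mis-attach arguments that only a parser or a trained model resolves.
The evaluation follows the track levels as described in prose, not the
official scorer's code, so edge-case conventions (averaging, deduplication)
are configuration rather than certainties. Dictionary coverage is the
bundled fixture set unless a user supplies real resource TSVs. Statement
inference (e.g. collapsing a decrease of a decrease), causal-direction
repair of associations, and `act()` inference are out of scope.
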