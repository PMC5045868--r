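# Bundled miniature vocabularies and worked examples.
#
# The fixture dictionary is intentionally minimal: it covers exactly the
# concepts exercised by the package's worked examples and tests (a handful of
# human/mouse/rat genes, chemicals, biological processes, one location, one
# anatomy term, one cell line), not any real curation vocabulary. Identifier
# spellings mirror the curation resources the toolkit is modeled on, even
# where current authority symbols differ.

.fx <- function(ns, value, cls, org = "none", syns = character(0)) {
  data.frame(namespace = ns, value = value, entity_class = cls,
             organism = org, synonyms = I(list(unique(c(value, syns)))),
             stringsAsFactors = FALSE)
}

#' Bundled fixture dictionaries
#'
#' A deterministic miniature dictionary bundle covering every concept used by
#' the package's worked examples: HGNC/MGI/RGD genes (with shared synonyms
#' such as SIRT1 and LXRalpha for organism-ranking demonstrations), ChEBI
#' chemicals, GO biological processes, the GOCC Nucleus location, a MeSH
#' process, a MeSH anatomy term and one cell line.
#'
#' @return A `bel_dictionary`.
#' @examples
#' dict_lookup(fixture_dictionaries(), "SREBP1a")
#' @export
fixture_dictionaries <- function() {
  rows <- list(
    .fx("HGNC", "EGR1", "gene_protein", "human",
        c("EGR-1", "early growth response-1")),
    .fx("HGNC", "FOXP3", "gene_protein", "human", "Foxp3"),
    .fx("HGNC", "IRF4", "gene_protein", "human", "IRF-4"),
    .fx("HGNC", "SREBF1", "gene_protein", "human", c("SREBP1a", "SREBP-1a")),
    .fx("HGNC", "EGFR", "gene_protein", "human", "EGF receptor"),
    .fx("HGNC", "TNFA", "gene_protein", "human",
        c("TNF-alpha", "tumor necrosis factor alpha")),
    .fx("HGNC", "TLR4", "gene_protein", "human", "LPS receptor"),
    .fx("HGNC", "AHR", "gene_protein", "human", "AhR"),
    .fx("HGNC", "NFAT1", "gene_protein", "human", c("NF-AT", "NFAT")),
    .fx("HGNC", "ADRBP1", "gene_protein", "human", "GRK2"),
    .fx("HGNC", "STAT4", "gene_protein", "human", "Stat4"),
    .fx("HGNC", "IL10", "gene_protein", "human",
        c("IL-10", "Interleukin 10", "interleukin-10")),
    .fx("HGNC", "FUS", "gene_protein", "human", "pigpen"),
    .fx("HGNC", "JUN", "gene_protein", "human", c("c-Jun", "c-jun")),
    .fx("HGNC", "FAS", "gene_protein", "human", "Fas"),
    .fx("HGNC", "HGF", "gene_protein", "human"),
    .fx("HGNC", "SIRT1", "gene_protein", "human"),
    .fx("MGI", "Sirt1", "gene_protein", "mouse", "SIRT1"),
    .fx("MGI", "Nr1h3", "gene_protein", "mouse", "LXRalpha"),
    .fx("RGD", "Sirt1", "gene_protein", "rat", "SIRT1"),
    .fx("RGD", "Nr1h3", "gene_protein", "rat", "LXRalpha"),
    .fx("SFAM", "AKT Family", "family", syns = "AKT"),
    .fx("SCOMP", "AP-1 Complex", "complex", syns = "AP-1"),
    .fx("CHEBI", "galangin", "chemical", syns = "Galangin"),
    .fx("CHEBI", "chondroitin sulfate", "chemical", "none",
        "chondroitin sulphate"),
    .fx("CHEBI", "N-acetyl-D-galactosamine", "chemical", "none",
        "N-acetyl-d-galactosamine"),
    .fx("CHEBI", "cadmium dichloride", "chemical", "none", c("CdCl2")),
    .fx("CHEBI", "corticosteroid", "chemical", "none", "corticosteroids"),
    .fx("SCHEM", "Lipopolysaccharide", "chemical", "none",
        c("lipopolysaccharide", "LPS")),
    .fx("GOBP", "cell death", "bioprocess"),
    .fx("GOBP", "response to ionizing radiation", "bioprocess", "none",
        "ionizing radiation"),
    .fx("GOCC", "Nucleus", "cell_structure", "none",
        c("nucleus", "nuclear")),
    .fx("MESHPP", "Oxidative Stress", "bioprocess", "none",
        "oxidative stress"),
    .fx("MESHD", "Atherosclerosis", "disease", "none", "atherosclerotic"),
    .fx("MESHAnatomy", "Liver", "anatomy", "none", c("liver", "livers")),
    .fx("CellLine", "MRC5CV1", "cell_line", "none", "MRC5CV1 cells"))
  bel_dictionary(do.call(rbind, rows))
}

# ---- worked-example event records -------------------------------------------

.demo_mention <- function(value, ns, cls = "gene_protein", surface = value) {
  list(ns = ns, value = value, entity_class = cls, surface = surface)
}

#' Worked event-to-BEL conversion examples
#'
#' Twelve event records spanning all nine event types, paired with the BEL
#' text each should translate to. These drive the conversion-rule test suite
#' and the acceptance script: gene expression vs transcription abundance
#' selection, phosphorylation sites, degradation, the three localization
#' dispatches, binding, and the three regulation types (including regulation
#' of another event and association from an undirected pair).
#'
#' @return A list of records, each with fields `id`, `sentence`, `event` (or
#'   `pair`) and `expected` (BEL text).
#' @export
demo_conversion_events <- function() {
  m <- list(
    EGR1 = .demo_mention("EGR1", "HGNC", surface = "early growth response-1"),
    FOXP3 = .demo_mention("FOXP3", "HGNC", surface = "Foxp3"),
    IRF4 = .demo_mention("IRF4", "HGNC", surface = "IRF-4"),
    SREBF1 = .demo_mention("SREBF1", "HGNC", surface = "SREBP1a"),
    EGFR = .demo_mention("EGFR", "HGNC", surface = "EGF receptor"),
    TNFA = .demo_mention("TNFA", "HGNC", surface = "TNF-alpha"),
    TLR4 = .demo_mention("TLR4", "HGNC"),
    AHR = .demo_mention("AHR", "HGNC", surface = "AhR"),
    NFAT1 = .demo_mention("NFAT1", "HGNC", surface = "NF-AT"),
    GRK2 = .demo_mention("ADRBP1", "HGNC", surface = "GRK2"),
    STAT4 = .demo_mention("STAT4", "HGNC"),
    IL10 = .demo_mention("IL10", "HGNC", surface = "Interleukin 10"),
    galangin = .demo_mention("galangin", "CHEBI", "chemical",
                             surface = "Galangin"))
  e8 <- list(type = "Localization", trigger = "translocation",
             theme = m$AHR, to_loc = "nuclear")
  e1 <- list(type = "Gene_expression", trigger = "express", theme = m$EGR1)
  list(
    list(id = "E1", sentence = "Early growth response-1 gene expression",
         event = e1, expected = "p(HGNC:EGR1)"),
    list(id = "E2", sentence = "Transfection of Foxp3",
         event = list(type = "Gene_expression", trigger = "transfection",
                      theme = m$FOXP3),
         expected = "r(HGNC:FOXP3)"),
    list(id = "E3", sentence = "IRF-4 transcription",
         event = list(type = "Transcription", trigger = "transcription",
                      theme = m$IRF4),
         expected = "r(HGNC:IRF4)"),
    list(id = "E4", sentence = "Phosphorylation of Thr-426 in SREBP1a",
         event = list(type = "Phosphorylation", trigger = "Phosphorylation",
                      theme = m$SREBF1, site = "Thr-426"),
         expected = "p(HGNC:SREBF1, pmod(P,T,426))"),
    list(id = "E5", sentence = "Degradation of the EGF receptor",
         event = list(type = "ProteinCatabolism", trigger = "degradation",
                      theme = m$EGFR),
         expected = "deg(p(HGNC:EGFR))"),
    list(id = "E6",
         sentence = "Cells treated with LPS secreted similar levels of TNF-alpha",
         event = list(type = "Localization", trigger = "secrete",
                      theme = m$TNFA),
         expected = "sec(p(HGNC:TNFA))"),
    list(id = "E7",
         sentence = "Surface expression of the LPS receptor complex that comprises TLR4.",
         event = list(type = "Localization", trigger = "express",
                      theme = m$TLR4, to_loc = "surface"),
         expected = "surf(p(HGNC:TLR4))"),
    list(id = "E8", sentence = "Galangin induced AhR nuclear translocation.",
         event = e8,
         expected = "tloc(p(HGNC:AHR),GOCC:Nucleus)"),
    list(id = "E9", sentence = "NF-AT interacts with Foxp3.",
         event = list(type = "Binding", trigger = "interacts",
                      theme = m$NFAT1, theme2 = m$FOXP3),
         expected = "complex(p(HGNC:NFAT1), p(HGNC:FOXP3))"),
    list(id = "E10", sentence = "Galangin induced AhR nuclear translocation.",
         event = list(type = "PositiveRegulation", trigger = "induce",
                      theme = e8, cause = m$galangin),
         expected = "a(CHEBI:galangin) -> tloc(p(HGNC:AHR),GOCC:Nucleus)"),
    list(id = "E11",
         sentence = "GRK2 decreases early growth response-1 expression.",
         event = list(type = "NegativeRegulation", trigger = "decrease",
                      theme = e1, cause = m$GRK2),
         expected = "p(HGNC:ADRBP1) -| p(HGNC:EGR1)"),
    list(id = "E12", sentence = "STAT4 controls Interleukin 10.",
         pair = list(entity1 = m$STAT4, entity2 = m$IL10),
         expected = "p(HGNC:STAT4) -- p(HGNC:IL10)"))
}

#' Worked scoring examples
#'
#' Four evidence sentences with gold and predicted BEL statement sets,
#' spanning an exact hit plus a spurious pair, a function-level mismatch
#' (`tloc` predicted where the gold annotates `act`), a complete miss built
#' from placeholder subjects, and partial credit for a nested gold statement.
#' Used by the scorer tests and the acceptance script.
#'
#' @return A list with one element per sentence: `sentence_id`, `sentence`,
#'   `gold` and `predicted` character vectors of BEL statements.
#' @export
demo_eval_corpus <- function() {
  list(
    list(
      sentence_id = "s1",
      sentence = paste("The nuclear protein pigpen has an affinity for",
                       "carbohydrate structures ... and can be preferentially",
                       "inhibited by saccharides, most notably",
                       "N-acetyl-d-galactosamine and chondroitin sulphate."),
      gold = c('a(CHEBI:"N-acetyl-D-galactosamine") -| p(HGNC:FUS)',
               'a(CHEBI:"chondroitin sulfate") -| p(HGNC:FUS)'),
      predicted = c('a(CHEBI:"N-acetyl-D-galactosamine") -| p(HGNC:FUS)',
                    'a(CHEBI:"N-acetyl-D-galactosamine") -| a(CHEBI:"chondroitin sulfate")')),
    list(
      sentence_id = "s2",
      sentence = paste("60 or 90 uM galangin induced AhR nuclear",
                       "translocation in both cell type."),
      gold = "a(CHEBI:galangin) -> act(p(HGNC:AHR))",
      predicted = "a(CHEBI:galangin) -> tloc(p(HGNC:AHR))"),
    list(
      sentence_id = "s3",
      sentence = paste("In the absence of CdCl2 pre-treatment, ionizing",
                       "radiation increased both expression and",
                       "phosphorylation of c-Jun in MRC5CV1 cells but not in",
                       "AT5BIVA cells."),
      gold = c('bp(GOBP:"response to ionizing radiation") -> p(HGNC:JUN,pmod(P))',
               'bp(GOBP:"response to ionizing radiation") -> p(HGNC:JUN)'),
      predicted = c('p(PH:placeholder) -| (a(CHEBI:"cadmium dichloride") -> p(HGNC:JUN,pmod(P)))',
                    'p(PH:placeholder) -| (a(CHEBI:"cadmium dichloride") -> p(HGNC:JUN))',
                    'p(HGNC:JUN) -- a(CHEBI:"cadmium dichloride")')),
    list(
      sentence_id = "s4",
      sentence = paste("The sensitivity to Fas-induced cell death was reduced",
                       "in HGF transfectants, which was reversed by the",
                       "presence of anti-HGF antibody."),
      gold = 'p(HGNC:HGF) -| (act(p(HGNC:FAS)) -> bp(GOBP:"cell death"))',
      predicted = c('p(PH:placeholder) -| (p(HGNC:FAS) -> bp(GOBP:"cell death"))',
                    'p(HGNC:FAS) -- bp(GOBP:"cell death")',
                    'p(HGNC:HGF) -- bp(GOBP:"cell death")')))
}
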