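# The chemical-search vocabulary: predicate and parameter IRIs recognized
# by the procedure-call extension.  The base IRI is configurable; queries
# must use whatever IRI the server is configured with.

.sachemDefaultBase <- "http://bioinfo.uochb.cas.cz/rdf/v1.0/sachem#"

#' Chemical-search vocabulary
#'
#' Returns the vocabulary used to recognize procedure-call patterns:
#' the two procedure predicates (`substructureSearch`, `similaritySearch`),
#' the argument properties (`query`, `topn`, `searchMode`, `tautomerMode`,
#' `chargeMode`, `isotopeMode`, `stereoMode`, `cutoff`), the mode value
#' IRIs, and the result properties of structured similarity hits
#' (`compound`, `score`).
#'
#' @param base vocabulary base IRI; all local names are resolved against it.
#' @return a named list with elements `base` and one full IRI (in `<...>`
#'   term encoding) per local name.
#' @export
sachemVocabulary <- function(base = .sachemDefaultBase) {
  locals <- c("substructureSearch", "similaritySearch", "exactSearch",
              "query", "topn", "searchMode", "tautomerMode", "chargeMode",
              "isotopeMode", "stereoMode", "cutoff",
              "ignoreTautomers", "inchiTautomers",
              "defaultChargeAsAny", "defaultChargeAsZero", "ignoreCharges",
              "defaultIsotopeAsStandard", "defaultIsotopeAsAny",
              "ignoreIsotopes", "strictStereo", "ignoreStereo",
              "compound", "score")
  out <- c(list(base = base),
           setNames(as.list(rdfIri(paste0(base, locals))), locals))
  out
}
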