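#' ChemSparql: interoperable chemical structure search over SPARQL
#'
#' A desk-scale implementation of a SPARQL endpoint whose query engine
#' recognizes chemical-search procedure calls encoded as ordinary triple
#' patterns, answering substructure and similarity searches over an
#' indexed small-molecule dataset.  See the package vignette for the
#' method description.
#'
#' @useDynLib ChemSparql, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"
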