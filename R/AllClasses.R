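#' @import methods
NULL

# -- Molecule -----------------------------------------------------------------

#' Molecule: a labeled chemical graph
#'
#' A `Molecule` stores atoms and bonds as data frames, mirroring a connection
#' table.  Atom annotations keep track of whether a property was written
#' explicitly in the input (`chargeSpecified`, `isotopeSpecified`,
#' `explicitH`), because the substructure-matching modes give unspecified
#' annotations wildcard or default semantics.
#'
#' Atom columns: `element`, `charge`, `chargeSpecified`, `isotope` (`NA` =
#' unlabeled), `isotopeSpecified`, `aromatic`, `explicitH` (`NA` =
#' unconstrained), `parity` (`"clockwise"`, `"anticlockwise"` or `NA`),
#' `totalH` and `inRing` (filled by [normalizeAromaticity()]).
#'
#' Bond columns: `a1`, `a2` (atom indices), `order` (`"single"`, `"double"`,
#' `"triple"`, `"aromatic"` or the tautomer-canonical `"tautomeric"`),
#' `config` (`"cis"`, `"trans"` or `NA`, double bonds only), `refA`, `refB`
#' (the reference substituents the configuration refers to), `inRing`.
#'
#' @slot atoms data.frame of atom annotations (one row per atom).
#' @slot bonds data.frame of bonds.
#' @slot tetraOrder list, one entry per atom: `NULL`, or the neighbor order
#'   (atom indices, `0` marking an implicit hydrogen) that the atom's
#'   tetrahedral parity refers to.
#' @slot source the original input string the molecule was read from.
#'
#' @seealso [parseSmiles()], [parseMolfile()], [normalizeAromaticity()]
#' @export
setClass("Molecule", representation(
  atoms = "data.frame",
  bonds = "data.frame",
  tetraOrder = "list",
  source = "character"
))

setValidity("Molecule", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character()
  if (nrow(a) < 1L) msgs <- c(msgs, "a molecule must have at least one atom")
  need <- c("element", "charge", "chargeSpecified", "isotope",
            "isotopeSpecified", "aromatic", "explicitH", "parity")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, "missing atom columns")
  if (nrow(b) > 0L) {
    if (any(b$a1 < 1L | b$a1 > nrow(a) | b$a2 < 1L | b$a2 > nrow(a)))
      msgs <- c(msgs, "bond atom index out of range")
    if (any(b$a1 == b$a2)) msgs <- c(msgs, "self-bond not allowed")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond")
    if (any(!is.na(b$config) & b$order != "double"))
      msgs <- c(msgs, "cis/trans configuration on a non-double bond")
  }
  if (length(object@tetraOrder) != nrow(a))
    msgs <- c(msgs, "tetraOrder must have one entry per atom")
  if (!all(is.na(a$explicitH) | a$explicitH >= 0L))
    msgs <- c(msgs, "explicitH must be >= 0")
  if (any(!a$chargeSpecified & a$charge != 0L))
    msgs <- c(msgs, "unspecified charge must be zero")
  if (any(!a$isotopeSpecified & !is.na(a$isotope)))
    msgs <- c(msgs, "unspecified isotope must be absent")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Molecule number of atoms.
#' @param x,object a `Molecule`.
#' @export
setMethod("length", "Molecule", function(x) nrow(x@atoms))

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d atoms, %d bonds", nrow(object@atoms),
              nrow(object@bonds)))
  if (nzchar(object@source))
    cat(sprintf("  [%s]", object@source))
  cat("\n")
  invisible(object)
})

#' Atom and bond tables of a molecule
#'
#' Accessors for the atom and bond data frames of a [Molecule-class].
#'
#' @param mol a `Molecule`.
#' @return `atoms()` and `bonds()` return data frames; `sourceText()` the
#'   original input string.
#' @export
atoms <- function(mol) mol@atoms

#' @rdname atoms
#' @export
bonds <- function(mol) mol@bonds

#' @rdname atoms
#' @export
sourceText <- function(mol) mol@source

#' @rdname atoms
#' @export
natoms <- function(mol) nrow(mol@atoms)

# -- Fingerprints -------------------------------------------------------------

#' Fingerprint classes
#'
#' Fingerprints are unfolded sets of 64-bit identifiers rendered as 16-digit
#' hexadecimal strings.  `SimFingerprint` holds Morgan-style circular
#' environment identifiers used for Jaccard similarity scoring;
#' `ScreenFingerprint` holds linear path features used as a subgraph-monotone
#' screen before substructure verification.
#'
#' @slot ids sorted character vector of distinct identifiers.
#' @aliases ScreenFingerprint-class
#' @export
setClass("SimFingerprint", representation(ids = "character"))

#' @rdname SimFingerprint-class
#' @export
setClass("ScreenFingerprint", representation(ids = "character"))

#' @param fp a fingerprint object.
#' @rdname SimFingerprint-class
#' @export
fingerprintIds <- function(fp) fp@ids

setMethod("show", "SimFingerprint", function(object) {
  cat(sprintf("SimFingerprint: %d identifiers\n", length(object@ids)))
  invisible(object)
})
setMethod("show", "ScreenFingerprint", function(object) {
  cat(sprintf("ScreenFingerprint: %d path features\n", length(object@ids)))
  invisible(object)
})

#' @rdname SimFingerprint-class
#' @export
setMethod("length", "SimFingerprint", function(x) length(x@ids))
#' @rdname SimFingerprint-class
#' @param x a fingerprint.
#' @export
setMethod("length", "ScreenFingerprint", function(x) length(x@ids))

# -- MatchOptions -------------------------------------------------------------

.searchModes  <- c("substructure", "exact")
.chargeModes  <- c("defaultChargeAsAny", "defaultChargeAsZero", "ignoreCharges")
.isotopeModes <- c("defaultIsotopeAsStandard", "defaultIsotopeAsAny",
                   "ignoreIsotopes")
.stereoModes  <- c("strictStereo", "ignoreStereo")
.tautomerModes <- c("ignoreTautomers", "inchiTautomers")

#' Structure-search matching options
#'
#' The parameter set governing substructure and exact matching semantics.
#' Unspecified query annotations are coalesced according to the selected
#' modes: e.g. under `defaultChargeAsAny` an atom written without a charge is
#' a wildcard that matches any formal charge, while under
#' `defaultChargeAsZero` it matches only uncharged atoms, and
#' `ignoreCharges` disregards charge annotations entirely.  Analogous
#' wildcard rules apply to isotopes.  `strictStereo` removes matches in which
#' defined query and target stereo descriptors contradict each other;
#' descriptors that are undefined on either side never conflict.
#'
#' @slot searchMode `"substructure"` or `"exact"`.
#' @slot chargeMode one of `"defaultChargeAsAny"`, `"defaultChargeAsZero"`,
#'   `"ignoreCharges"`.
#' @slot isotopeMode one of `"defaultIsotopeAsStandard"`,
#'   `"defaultIsotopeAsAny"`, `"ignoreIsotopes"`.
#' @slot stereoMode `"strictStereo"` or `"ignoreStereo"`.
#' @slot tautomerMode `"ignoreTautomers"` or `"inchiTautomers"`.
#' @export
setClass("MatchOptions", representation(
  searchMode = "character",
  chargeMode = "character",
  isotopeMode = "character",
  stereoMode = "character",
  tautomerMode = "character"
))

setValidity("MatchOptions", function(object) {
  msgs <- character()
  chk <- function(v, allowed, what)
    if (length(v) != 1L || !v %in% allowed)
      sprintf("%s must be one of: %s", what, paste(allowed, collapse = ", "))
  msgs <- c(msgs,
            chk(object@searchMode, .searchModes, "searchMode"),
            chk(object@chargeMode, .chargeModes, "chargeMode"),
            chk(object@isotopeMode, .isotopeModes, "isotopeMode"),
            chk(object@stereoMode, .stereoModes, "stereoMode"),
            chk(object@tautomerMode, .tautomerModes, "tautomerMode"))
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MatchOptions constructor with the service defaults
#'   (substructure search, unspecified charge as wildcard, unspecified
#'   isotope as the standard isotope, stereochemistry ignored, tautomerism
#'   ignored).
#' @param searchMode,chargeMode,isotopeMode,stereoMode,tautomerMode see slots.
#' @export
matchOptions <- function(searchMode = "substructure",
                         chargeMode = "defaultChargeAsAny",
                         isotopeMode = "defaultIsotopeAsStandard",
                         stereoMode = "ignoreStereo",
                         tautomerMode = "ignoreTautomers") {
  new("MatchOptions", searchMode = searchMode, chargeMode = chargeMode,
      isotopeMode = isotopeMode, stereoMode = stereoMode,
      tautomerMode = tautomerMode)
}

setMethod("show", "MatchOptions", function(object) {
  cat("MatchOptions:",
      object@searchMode, object@chargeMode, object@isotopeMode,
      object@stereoMode, object@tautomerMode, "\n")
  invisible(object)
})

# -- CompoundIndex ------------------------------------------------------------

#' An indexed compound dataset
#'
#' Holds the parsed, normalized molecules of a dataset together with their
#' screening and similarity fingerprints, keyed by compound IRI.  Record
#' order is load order and determines the result order of substructure
#' searches.
#'
#' @slot name dataset label.
#' @slot iris character vector of compound IRIs (unique).
#' @slot molecules list of [Molecule-class] objects.
#' @slot screenIds list of character vectors (path-feature identifiers).
#' @slot simIds list of character vectors (Morgan environment identifiers).
#' @slot skipped number of input records that failed to parse and were
#'   skipped at build time.
#' @seealso [buildIndex()], [substructureSearch()], [similaritySearch()]
#' @export
setClass("CompoundIndex", representation(
  name = "character",
  iris = "character",
  molecules = "list",
  screenIds = "list",
  simIds = "list",
  skipped = "integer"
))

setValidity("CompoundIndex", function(object) {
  n <- length(object@iris)
  if (anyDuplicated(object@iris)) return("compound IRIs must be unique")
  if (length(object@molecules) != n || length(object@screenIds) != n ||
      length(object@simIds) != n)
    return("record slots must be parallel to iris")
  TRUE
})

#' @describeIn CompoundIndex number of indexed compounds.
#' @param x,object a `CompoundIndex`.
#' @export
setMethod("length", "CompoundIndex", function(x) length(x@iris))

setMethod("show", "CompoundIndex", function(object) {
  cat(sprintf("CompoundIndex '%s': %d compounds", object@name,
              length(object@iris)))
  if (object@skipped > 0L)
    cat(sprintf(" (%d records skipped at build)", object@skipped))
  cat("\n")
  invisible(object)
})

#' @rdname CompoundIndex-class
#' @param index a `CompoundIndex`.
#' @export
compoundIris <- function(index) index@iris

#' @rdname CompoundIndex-class
#' @param iri a compound IRI present in the index.
#' @export
compoundMolecule <- function(index, iri) {
  i <- match(iri, index@iris)
  if (is.na(i)) stop("unknown compound IRI: ", iri)
  index@molecules[[i]]
}

# -- RDF graph ----------------------------------------------------------------

#' In-memory RDF graph
#'
#' A set of triples over encoded RDF terms (see [rdfIri()] for the term
#' encoding).  Loaded from Turtle or N-Triples text and queried by the
#' SPARQL evaluator.
#'
#' @slot triples data.frame with character columns `s`, `p`, `o`.
#' @seealso [parseTurtle()], [parseNTriples()], [evaluateQuery()]
#' @export
setClass("RdfGraph", representation(triples = "data.frame"))

#' @describeIn RdfGraph number of triples.
#' @param x,object an `RdfGraph`.
#' @export
setMethod("length", "RdfGraph", function(x) nrow(x@triples))

setMethod("show", "RdfGraph", function(object) {
  cat(sprintf("RdfGraph: %d triples\n", nrow(object@triples)))
  invisible(object)
})

#' @rdname RdfGraph-class
#' @param graph an `RdfGraph`.
#' @export
rdfTriples <- function(graph) graph@triples

#' @rdname RdfGraph-class
#' @param triples data.frame with columns `s`, `p`, `o` of encoded terms.
#' @export
rdfGraph <- function(triples = data.frame(s = character(), p = character(),
                                          o = character(),
                                          stringsAsFactors = FALSE)) {
  new("RdfGraph", triples = triples[, c("s", "p", "o")])
}

# -- SPARQL query plan --------------------------------------------------------

#' Parsed SPARQL query
#'
#' The deterministic evaluation plan produced by [parseSparql()]: projected
#' variables, basic graph pattern, filters and solution modifiers.
#'
#' @slot variables projected variable names (without `?`); `"*"` selects all.
#' @slot distinct logical, `SELECT DISTINCT`.
#' @slot patterns data.frame (`s`, `p`, `o`) of encoded terms; variables are
#'   encoded as `?name`, blank nodes as `_:label`.
#' @slot filters list of filter expression trees.
#' @slot orderBy data.frame with columns `var`, `desc`.
#' @slot limit,offset integer or `NA`.
#' @slot prefixes named character vector of prefix expansions.
#' @export
setClass("SparqlQuery", representation(
  variables = "character",
  distinct = "logical",
  patterns = "data.frame",
  filters = "list",
  orderBy = "data.frame",
  limit = "integer",
  offset = "integer",
  prefixes = "character"
))

setMethod("show", "SparqlQuery", function(object) {
  cat(sprintf("SparqlQuery: SELECT %s; %d triple patterns, %d filters\n",
              paste(object@variables, collapse = " "),
              nrow(object@patterns), length(object@filters)))
  invisible(object)
})

# -- SPARQL result set --------------------------------------------------------

#' SPARQL result set
#'
#' An ordered list of solution rows over a fixed set of variables, the
#' payload serialized to the four standard result formats.
#'
#' @slot variables ordered variable names (without `?`).
#' @slot bindings data.frame of encoded RDF terms, one column per variable;
#'   `NA` marks an unbound variable.
#' @seealso [serializeResults()], [parseResults()]
#' @export
setClass("ResultSet", representation(
  variables = "character",
  bindings = "data.frame"
))

setValidity("ResultSet", function(object) {
  if (!identical(names(object@bindings), object@variables) &&
      !(length(object@variables) == 0L && ncol(object@bindings) == 0L))
    return("binding columns must equal the variable list")
  TRUE
})

#' @rdname ResultSet-class
#' @param variables character vector of variable names.
#' @param bindings data.frame of encoded terms (columns = variables).
#' @export
resultSet <- function(variables, bindings = NULL) {
  if (is.null(bindings)) {
    bindings <- as.data.frame(setNames(rep(list(character()),
                                           length(variables)), variables),
                              stringsAsFactors = FALSE, check.names = FALSE)
  }
  new("ResultSet", variables = as.character(variables), bindings = bindings)
}

#' @describeIn ResultSet number of solution rows.
#' @param x,object a `ResultSet`.
#' @export
setMethod("length", "ResultSet", function(x) nrow(x@bindings))

setMethod("show", "ResultSet", function(object) {
  cat(sprintf("ResultSet: %d rows over %d variables (%s)\n",
              nrow(object@bindings), length(object@variables),
              paste(object@variables, collapse = ", ")))
  invisible(object)
})

#' @rdname ResultSet-class
#' @param rs a `ResultSet`.
#' @export
resultBindings <- function(rs) rs@bindings

#' @rdname ResultSet-class
#' @export
resultVariables <- function(rs) rs@variables
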