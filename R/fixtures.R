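# Deterministic synthetic dataset generator.  Molecules are composed from
# vetted SMILES grammar templates (never random graphs), so every generated
# structure is chemically sensible and parseable by construction.  All
# randomness comes from the seed in the spec; the same spec yields
# byte-identical output.

.fixtureFamilies <- c("alkane", "alcohol", "amine", "aromatic", "charged",
                      "isotopic", "stereo", "fused-ring")

#' Synthetic dataset specification
#'
#' @param seed integer seed driving all randomness.
#' @param nMolecules number of molecules to emit (>= 1).
#' @param families molecule families to span; defaults to all eight.
#' @param iriBase IRI prefix for generated compound IRIs.
#' @return a `fixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, nMolecules = 40L,
                        families = .fixtureFamilies,
                        iriBase = "http://example.org/compound/") {
  stopifnot(nMolecules >= 1L, length(families) >= 1L,
            all(families %in% .fixtureFamilies))
  structure(list(seed = as.integer(seed), nMolecules = as.integer(nMolecules),
                 families = families, iriBase = iriBase),
            class = "fixtureSpec")
}

# guaranteed structure pairs per family: each entry is the base member plus
# a related member (substructure-related, or differing only in the probed
# annotation)
.familySeeds <- list(
  alkane = c("CCC", "CCCC"),
  alcohol = c("CCO", "CCCO"),
  amine = c("CCN", "CCCN"),
  aromatic = c("c1ccccc1", "Cc1ccccc1"),
  charged = c("CC(=O)O", "CC(=O)[O-]"),
  isotopic = c("CO", "[13CH3]O"),
  stereo = c("F/C=C/F", "F/C=C\\F"),
  `fused-ring` = c("c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1"))

# random decorated chain from a tiny template grammar
.randomTemplate <- function(family) {
  chain <- function(n) paste(rep("C", n), collapse = "")
  n <- sample(2:8, 1L)
  base <- switch(family,
    alkane = chain(n),
    alcohol = paste0(chain(n), "O"),
    amine = paste0(chain(n), "N"),
    aromatic = sample(c("c1ccccc1", "c1ccncc1", "Cc1ccccc1",
                        "Oc1ccccc1", "Nc1ccccc1",
                        paste0(chain(sample(1:3, 1L)), "c1ccccc1")), 1L),
    charged = sample(c("C[N+](C)(C)C", "CC(=O)[O-]", "CC[N+](C)(C)C",
                       "CCC(=O)[O-]"), 1L),
    isotopic = sample(c("[13CH3]O", paste0("[13CH3]", chain(n - 1L)),
                        "[13CH3]CO"), 1L),
    stereo = sample(c("C/C=C/C", "C/C=C\\C", "CC[C@H](N)C(=O)O",
                      "CC[C@@H](N)C(=O)O", "F/C=C/Cl", "F/C=C\\Cl"), 1L),
    `fused-ring` = sample(c("c1ccc2ccccc2c1", "Nc1ncnc2[nH]cnc12",
                            "c1ccc2[nH]ccc2c1", "Cc1ccc2ccccc2c1"), 1L))
  # occasional methyl decoration on plain chains
  if (family %in% c("alkane", "alcohol", "amine") && n > 3L &&
      stats::runif(1) < 0.4)
    base <- paste0("CC(C)", substring(base, 3L))
  base
}

#' Generate the synthetic molecule dataset
#'
#' Emits an (IRI, SMILES) table spanning the requested families together
#' with a Turtle companion graph carrying one label and one numeric
#' property (heavy atom count) per compound, so that join queries are
#' exercisable.  The output always contains, when the corresponding family
#' is requested: one substructure-related pair per family, a pair differing
#' only by a formal charge, an isotopically labeled / plain pair, a
#' cis/trans pair, and one pair of identical structures written in
#' different atom orders.  Identical specs produce identical bytes.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `smilesTable` (data.frame `iri`, `structure`,
#'   `format`) and `turtle` (character scalar).
#' @export
generateFixtures <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "fixtureSpec"))
  seeds <- unlist(.familySeeds[spec$families], use.names = FALSE)
  if (spec$nMolecules < length(seeds))
    stop(sprintf(paste("nMolecules = %d cannot satisfy the guarantees of",
                       "the requested families (need at least %d)"),
         spec$nMolecules, length(seeds)))
  guaranteed <- seeds
  # the identical-structure / different-atom-order pair, when there is room
  if (spec$nMolecules >= length(seeds) + 2L)
    guaranteed <- c(guaranteed, "CCO", "OCC")

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec$seed)

  smiles <- guaranteed
  while (length(smiles) < spec$nMolecules) {
    fam <- sample(spec$families, 1L)
    smiles <- c(smiles, .randomTemplate(fam))
  }
  iris <- paste0(spec$iriBase, sprintf("M%04d", seq_along(smiles)))

  heavy <- vapply(smiles, function(s) natoms(parseSmiles(s)), 1L,
                  USE.NAMES = FALSE)
  turtle <- c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix ex: <http://example.org/prop/> .",
    "",
    unlist(lapply(seq_along(smiles), function(i) {
      sprintf("<%s> rdfs:label \"compound %d\" ; ex:heavyAtoms %d .",
              iris[i], i, heavy[i])
    })))

  list(smilesTable = data.frame(iri = iris, structure = smiles,
                                format = "smiles", stringsAsFactors = FALSE),
       turtle = paste(turtle, collapse = "\n"))
}

#' Write fixture files
#'
#' Writes `fixtures.tsv` (the SMILES table) and `fixtures.ttl` (the Turtle
#' companion graph) into a directory.  Deterministic: the same spec always
#' writes identical bytes.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if missing).
#' @return the two file paths, invisibly.
#' @export
writeFixtures <- function(spec = fixtureSpec(), dir = ".") {
  fx <- generateFixtures(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "fixtures.tsv")
  ttl <- file.path(dir, "fixtures.ttl")
  con <- file(tsv, "wb")
  writeLines(c("# synthetic compound dataset",
               paste(fx$smilesTable$iri, fx$smilesTable$structure,
                     sep = "\t")), con)
  close(con)
  con <- file(ttl, "wb")
  writeLines(fx$turtle, con)
  close(con)
  invisible(c(tsv, ttl))
}

#' Curated worked-example molecules and queries
#'
#' The molecules used throughout the documentation and tests: adenine and
#' adenosine (the tautomer-aware substructure example), ethanol, acetic
#' acid, benzene, tetramethylammonium, 13C-labeled methanol and the
#' cis/trans difluoroethene pair, together with ready-made SPARQL query
#' texts for the substructure and similarity procedure calls.
#'
#' @return list with elements `molecules` (named character vector of
#'   SMILES) and `queries` (named character vector of SPARQL texts).
#' @export
workedExamples <- function() {
  vocabBase <- .sachemDefaultBase
  molecules <- c(
    adenine = "Nc1ncnc2[nH]cnc12",
    adenosine = "OC[C@H]1O[C@@H](n2cnc3c(N)ncnc32)[C@H](O)[C@H]1O",
    ethanol = "CCO",
    aceticAcid = "CC(=O)O",
    benzene = "c1ccccc1",
    tetramethylammonium = "C[N+](C)(C)C",
    methanol13C = "[13CH3]O",
    cisDifluoroethene = "F/C=C\\F",
    transDifluoroethene = "F/C=C/F")
  queries <- c(
    substructure = paste0(
      "PREFIX sachem: <", vocabBase, ">\n",
      "SELECT ?COMPOUND WHERE {\n",
      "  ?COMPOUND sachem:substructureSearch [\n",
      "      sachem:query \"", molecules[["adenine"]], "\" ;\n",
      "      sachem:tautomerMode sachem:inchiTautomers ].\n",
      "}\n"),
    similarity = paste0(
      "PREFIX sachem: <", vocabBase, ">\n",
      "SELECT ?COMPOUND ?SCORE WHERE {\n",
      "  [ sachem:compound ?COMPOUND ;\n",
      "    sachem:score ?SCORE ] sachem:similaritySearch [\n",
      "      sachem:query \"", molecules[["adenine"]], "\" ;\n",
      "      sachem:cutoff 0.5 ].\n",
      "}\n"))
  list(molecules = molecules, queries = queries)
}
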