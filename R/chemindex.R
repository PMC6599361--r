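# The indexed compound dataset and the search procedures the SPARQL layer
# invokes: substructure (screen + verify), exact, and fingerprint
# similarity.

.parseStructure <- function(text, format = c("smiles", "molfile")) {
  format <- match.arg(format)
  if (format == "smiles") parseSmiles(text) else parseMolfile(text)
}

.queryError <- function(msg) {
  stop(structure(class = c("queryEvaluationError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Build a compound index
#'
#' Parses, normalizes and fingerprints every entry of a dataset.  Entries
#' that fail to parse or normalize are skipped with a warning; the skipped
#' count is kept on the index.  Duplicate IRIs are an error.
#'
#' @param entries data.frame with columns `iri`, `structure` and `format`
#'   (`"smiles"` or `"molfile"`; recycled if a single value), e.g. as
#'   returned by [readSmilesTable()] or [readSdfDataset()].
#' @param name dataset label.
#' @return a [CompoundIndex-class].
#' @examples
#' idx <- buildIndex(data.frame(iri = c("ex:1", "ex:2"),
#'                              structure = c("CCO", "c1ccccc1"),
#'                              format = "smiles"))
#' length(idx)
#' @export
buildIndex <- function(entries, name = "dataset") {
  stopifnot(is.data.frame(entries), all(c("iri", "structure") %in% names(entries)))
  if (is.null(entries$format)) entries$format <- "smiles"
  if (anyDuplicated(entries$iri))
    stop("duplicate compound IRI: ",
         entries$iri[duplicated(entries$iri)][1L])
  iris <- character(); mols <- list(); sfp <- list(); mfp <- list()
  skipped <- 0L
  for (k in seq_len(nrow(entries))) {
    mol <- tryCatch(
      normalizeAromaticity(.parseStructure(entries$structure[k],
                                           entries$format[k])),
      error = function(e) e)
    if (inherits(mol, "error")) {
      warning(sprintf("skipping %s: %s", entries$iri[k],
                      conditionMessage(mol)), call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    i <- length(iris) + 1L
    iris[i] <- entries$iri[k]
    mols[[i]] <- mol
    sfp[[i]] <- screenFingerprint(mol)@ids
    mfp[[i]] <- morganFingerprint(mol)@ids
  }
  new("CompoundIndex", name = name, iris = iris, molecules = mols,
      screenIds = sfp, simIds = mfp, skipped = skipped)
}

.parseQueryStructure <- function(queryText, format) {
  mol <- tryCatch(.parseStructure(queryText, format), error = function(e) e)
  if (inherits(mol, "error"))
    .queryError(paste0("cannot parse query structure: ",
                       conditionMessage(mol)))
  mol <- tryCatch(normalizeAromaticity(mol), error = function(e) e)
  if (inherits(mol, "error"))
    .queryError(paste0("cannot normalize query structure: ",
                       conditionMessage(mol)))
  mol
}

#' Substructure search over an index
#'
#' Returns the IRIs of compounds containing the query structure, in dataset
#' load order.  Candidates are pre-filtered with the path-feature subset
#' test ([screenFingerprint()]) and then verified by subgraph isomorphism
#' ([molMatches()]); the screen affects speed only, never results.  With
#' `tautomerMode = "inchiTautomers"` the screen is bypassed and every
#' record is verified directly, because the canonicalized bond classes are
#' outside the screening label alphabet.
#'
#' @param index a [CompoundIndex-class].
#' @param queryText the query structure, SMILES or MDL molfile.
#' @param format `"smiles"` or `"molfile"`.
#' @param opts a [MatchOptions-class].
#' @param topn maximum number of results; `NULL` means unlimited.
#' @return character vector of compound IRIs.
#' @examples
#' idx <- buildIndex(data.frame(iri = c("ex:1", "ex:2", "ex:3"),
#'                              structure = c("CCO", "CC(=O)O", "c1ccccc1")))
#' substructureSearch(idx, "CO")
#' @export
substructureSearch <- function(index, queryText, format = "smiles",
                               opts = matchOptions(), topn = NULL) {
  if (!is.null(topn) && (!is.numeric(topn) || topn < 0))
    .queryError("topn must be a non-negative integer")
  qmol <- .parseQueryStructure(queryText, format)
  useScreen <- opts@tautomerMode != "inchiTautomers"
  qscreen <- if (useScreen) screenFingerprint(qmol)@ids else NULL
  hits <- character()
  for (i in seq_along(index@iris)) {
    if (!is.null(topn) && length(hits) >= topn) break
    if (useScreen && !.screenSubset(qscreen, index@screenIds[[i]])) next
    if (molMatches(qmol, index@molecules[[i]], opts))
      hits <- c(hits, index@iris[i])
  }
  if (!is.null(topn) && length(hits) > topn) hits <- hits[seq_len(topn)]
  hits
}

#' Exact-structure search over an index
#'
#' [substructureSearch()] with `searchMode = "exact"`: the query must map
#' onto the whole compound, hydrogen counts included.
#'
#' @inheritParams substructureSearch
#' @return character vector of compound IRIs.
#' @export
exactSearch <- function(index, queryText, format = "smiles",
                        opts = matchOptions(), topn = NULL) {
  opts@searchMode <- "exact"
  substructureSearch(index, queryText, format, opts, topn)
}

#' Fingerprint similarity search over an index
#'
#' Scores every record by Jaccard similarity between the Morgan
#' fingerprints of the query and the compound, keeps scores at or above the
#' cutoff, and sorts by descending score with ties broken by IRI.
#'
#' @inheritParams substructureSearch
#' @param cutoff minimum similarity score in `[0, 1]`; the service default
#'   is 0.8, and the comparison is inclusive.
#' @return data.frame with columns `compound` (IRI) and `score`.
#' @examples
#' idx <- buildIndex(data.frame(iri = c("ex:1", "ex:2"),
#'                              structure = c("CCO", "c1ccccc1")))
#' similaritySearch(idx, "CCO", cutoff = 0)
#' @export
similaritySearch <- function(index, queryText, format = "smiles",
                             cutoff = 0.8, topn = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1)
    .queryError("cutoff must be a number in [0, 1]")
  if (!is.null(topn) && (!is.numeric(topn) || topn < 0))
    .queryError("topn must be a non-negative integer")
  qmol <- .parseQueryStructure(queryText, format)
  qfp <- morganFingerprint(qmol)@ids
  scores <- vapply(index@simIds, function(ids) jaccardSimilarity(qfp, ids),
                   numeric(1))
  keep <- which(scores >= cutoff)
  ord <- keep[order(-scores[keep], index@iris[keep])]
  if (!is.null(topn) && length(ord) > topn) ord <- ord[seq_len(topn)]
  data.frame(compound = index@iris[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

# -- dataset loading ----------------------------------------------------------

#' Read a SMILES table
#'
#' Tab-separated file with one `IRI<TAB>SMILES` record per line; lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path file path (or a character vector of lines).
#' @return data.frame with columns `iri`, `structure`, `format`.
#' @export
readSmilesTable <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else path
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed SMILES table line: ", lines[bad][1L])
  data.frame(iri = vapply(parts, `[`, "", 1L),
             structure = vapply(parts, `[`, "", 2L),
             format = "smiles", stringsAsFactors = FALSE)
}

#' Read an SDF dataset
#'
#' Loads a multi-record SDF where each record carries its compound IRI in a
#' data field.
#'
#' @param path SDF file path or content.
#' @param iriField name of the data field holding the compound IRI.
#' @return data.frame with columns `iri`, `structure`, `format`.
#' @export
readSdfDataset <- function(path, iriField = "IDSM_IRI") {
  recs <- readSdf(path)
  iris <- vapply(recs, function(r) {
    v <- r$fields[iriField]
    if (is.na(v)) stop("SDF record without an ", iriField, " field")
    unname(v)
  }, character(1))
  data.frame(iri = iris,
             structure = vapply(recs, `[[`, "", "molfile"),
             format = "molfile", stringsAsFactors = FALSE)
}

# -- persistence --------------------------------------------------------------

.indexFormatVersion <- 1L

#' Save / load a compound index
#'
#' Single-file serialization of a [CompoundIndex-class] (plus an optional
#' companion RDF graph).  The format is private but versioned and stable
#' within a release.
#'
#' @param index a [CompoundIndex-class].
#' @param path file path.
#' @param graph optional [RdfGraph-class] stored alongside the index.
#' @return `loadIndex()` returns a list with elements `index` and `graph`
#'   (`NULL` when none was stored).
#' @export
saveIndex <- function(index, path, graph = NULL) {
  stopifnot(is(index, "CompoundIndex"))
  payload <- list(version = .indexFormatVersion,
                  name = index@name, iris = index@iris,
                  sources = vapply(index@molecules, sourceText, ""),
                  formats = vapply(index@molecules, function(m)
                    if (grepl("V2000", m@source)) "molfile" else "smiles", ""),
                  skipped = index@skipped,
                  graph = if (is.null(graph)) NULL else graph@triples)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$version, .indexFormatVersion))
    stop("unsupported index format version: ", payload$version)
  idx <- buildIndex(data.frame(iri = payload$iris,
                               structure = payload$sources,
                               format = payload$formats,
                               stringsAsFactors = FALSE),
                    name = payload$name)
  graph <- if (is.null(payload$graph)) NULL else rdfGraph(payload$graph)
  list(index = idx, graph = graph)
}
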