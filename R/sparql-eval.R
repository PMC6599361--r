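# Query evaluation: recognition of chemical-search procedure-call patterns
# inside the basic graph pattern, execution of the searches against a
# CompoundIndex, and joining of procedure outputs with residual triple
# patterns over the RDF store.

# zero-column data.frame with n rows (the identity/cardinality solution set)
.unitSolutions <- function(n = 1L) {
  structure(list(), class = "data.frame", row.names = seq_len(n),
            names = character())
}

# natural join of two solution data.frames (columns = encoded var/bnode
# tokens); preserves left-then-right row order, nested-loop, deterministic
.joinSolutions <- function(left, right) {
  common <- intersect(names(left), names(right))
  if (!nrow(left) || !nrow(right)) {
    out <- cbind(left[integer(0), , drop = FALSE],
                 right[integer(0), setdiff(names(right), common), drop = FALSE])
    return(out)
  }
  if (!length(common)) {
    li <- rep(seq_len(nrow(left)), each = nrow(right))
    ri <- rep(seq_len(nrow(right)), times = nrow(left))
  } else {
    lk <- do.call(paste, c(left[common], sep = "\r"))
    rk <- do.call(paste, c(right[common], sep = "\r"))
    li <- integer(0); ri <- integer(0)
    rIdxByKey <- split(seq_len(nrow(right)), rk)
    for (i in seq_len(nrow(left))) {
      hits <- rIdxByKey[[lk[i]]]
      if (!is.null(hits)) {
        li <- c(li, rep(i, length(hits)))
        ri <- c(ri, hits)
      }
    }
  }
  extra <- setdiff(names(right), common)
  out <- left[li, , drop = FALSE]
  for (cn in extra) out[[cn]] <- right[[cn]][ri]
  rownames(out) <- NULL
  out
}

# match one triple pattern against a triple table; returns a solution df
.matchPattern <- function(pattern, triples) {
  keep <- rep(TRUE, nrow(triples))
  varCols <- list()
  for (slot in c("s", "p", "o")) {
    tm <- pattern[[slot]]
    if (isVarTerm(tm) || isBlankTerm(tm)) {
      if (!is.null(varCols[[tm]])) {
        keep <- keep & (triples[[slot]] == triples[[varCols[[tm]]]])
      } else varCols[[tm]] <- slot
    } else {
      keep <- keep & (triples[[slot]] == tm)
    }
  }
  rows <- which(keep)
  out <- .unitSolutions(length(rows))
  for (tm in names(varCols)) out[[tm]] <- triples[[varCols[[tm]]]][rows]
  out
}

# -- procedure-call detection -------------------------------------------------

#' Detect procedure-call patterns in a basic graph pattern
#'
#' Scans the triple patterns for the chemical-search predicates.  A pattern
#' whose predicate is the substructure or similarity search predicate is a
#' procedure call: its object must be a blank node, and every pattern whose
#' subject is that blank node supplies one named argument.  Omitted
#' parameters take the documented defaults.  All other patterns are
#' returned as the residual graph pattern.
#'
#' @param patterns data.frame (`s`, `p`, `o`) of encoded terms, e.g.
#'   `query@patterns` from [parseSparql()].
#' @param vocab the vocabulary, from [sachemVocabulary()].
#' @return list with `invocations` (list of procedure invocations, each
#'   with `procedure`, `resultNode`, `args`) and `residual` (data.frame of
#'   the remaining patterns).
#' @export
detectProcedures <- function(patterns, vocab = sachemVocabulary()) {
  procPred <- c(substructureSearch = vocab$substructureSearch,
                similaritySearch = vocab$similaritySearch)
  isProc <- patterns$p %in% procPred
  if (!any(isProc))
    return(list(invocations = list(), residual = patterns))

  consumed <- logical(nrow(patterns))
  invocations <- list()
  modeMaps <- list(
    searchMode = c(setNames("substructure", vocab$substructureSearch),
                   setNames("exact", vocab$exactSearch)),
    tautomerMode = c(setNames("ignoreTautomers", vocab$ignoreTautomers),
                     setNames("inchiTautomers", vocab$inchiTautomers)),
    chargeMode = c(setNames("defaultChargeAsAny", vocab$defaultChargeAsAny),
                   setNames("defaultChargeAsZero", vocab$defaultChargeAsZero),
                   setNames("ignoreCharges", vocab$ignoreCharges)),
    isotopeMode = c(setNames("defaultIsotopeAsStandard",
                             vocab$defaultIsotopeAsStandard),
                    setNames("defaultIsotopeAsAny", vocab$defaultIsotopeAsAny),
                    setNames("ignoreIsotopes", vocab$ignoreIsotopes)),
    stereoMode = c(setNames("strictStereo", vocab$strictStereo),
                   setNames("ignoreStereo", vocab$ignoreStereo)))
  argProps <- list(
    substructureSearch = c(query = vocab$query, topn = vocab$topn,
                           searchMode = vocab$searchMode,
                           tautomerMode = vocab$tautomerMode,
                           chargeMode = vocab$chargeMode,
                           isotopeMode = vocab$isotopeMode,
                           stereoMode = vocab$stereoMode),
    similaritySearch = c(query = vocab$query, topn = vocab$topn,
                         cutoff = vocab$cutoff))

  for (pi in which(isProc)) {
    proc <- names(procPred)[match(patterns$p[pi], procPred)]
    argNode <- patterns$o[pi]
    if (!isBlankTerm(argNode))
      .queryError(paste0("the object of sachem:", proc,
                         " must be a blank node carrying the arguments"))
    consumed[pi] <- TRUE
    props <- argProps[[proc]]
    args <- list()
    for (ai in which(patterns$s == argNode)) {
      if (ai == pi) next
      consumed[ai] <- TRUE
      key <- names(props)[match(patterns$p[ai], props)]
      if (is.na(key))
        .queryError(paste0("unknown argument property ", patterns$p[ai],
                           " for sachem:", proc))
      val <- patterns$o[ai]
      if (isVarTerm(val))
        .unsupportedFeature("variable procedure arguments")
      if (key == "query") {
        if (!isLiteralTerm(val))
          .queryError("sachem:query must be a string literal")
        args$query <- termValue(val)
      } else if (key == "topn") {
        n <- .termNumeric(val)
        if (is.na(n) || n < 0)
          .queryError("sachem:topn must be a non-negative integer")
        args$topn <- as.integer(n)
      } else if (key == "cutoff") {
        x <- .termNumeric(val)
        if (is.na(x) || x < 0 || x > 1)
          .queryError("sachem:cutoff must be a number in [0, 1]")
        args$cutoff <- x
      } else {
        mode <- modeMaps[[key]][val]
        if (is.na(mode))
          .queryError(paste0("invalid value ", val, " for sachem:", key))
        args[[key]] <- unname(mode)
      }
    }
    if (is.null(args$query))
      .queryError(paste0("sachem:", proc, " call without the mandatory ",
                         "sachem:query argument"))
    invocations[[length(invocations) + 1L]] <-
      list(procedure = proc, resultNode = patterns$s[pi], args = args,
           argNode = argNode)
  }

  residual <- patterns[!consumed, , drop = FALSE]
  rownames(residual) <- NULL
  for (inv in invocations) {
    if (any(residual$s == inv$argNode | residual$o == inv$argNode))
      .queryError("procedure argument node used outside the procedure call")
  }
  list(invocations = invocations, residual = residual)
}

# auto-detect the structure encoding of a query argument
.structureFormat <- function(text) {
  if (grepl("V2000", text) || grepl("\n", text)) "molfile" else "smiles"
}

.formatDouble <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  s
}

#' Run a single procedure invocation
#'
#' Executes a detected procedure call against a compound index.  A
#' substructure (or exact) search binds the pattern's subject directly to
#' each matching compound IRI: the result is unstructured.  A similarity
#' search returns structured results: the subject is bound to a fresh blank
#' node per hit, and virtual triples attach the compound IRI and the
#' similarity score (an `xsd:double` literal) to that node so residual
#' patterns can pick them up.  Virtual triples exist only while the query
#' that created them is being evaluated; they are never added to the store.
#'
#' @param inv an invocation from [detectProcedures()].
#' @param index a [CompoundIndex-class].
#' @param vocab the vocabulary, from [sachemVocabulary()].
#' @param bnodePrefix label prefix for the fresh blank nodes.
#' @return list with `solutions` (data.frame keyed by encoded var/bnode
#'   tokens) and `virtual` (data.frame of virtual triples).
#' @export
runInvocation <- function(inv, index, vocab = sachemVocabulary(),
                          bnodePrefix = "proc1") {
  a <- inv$args
  fmt <- .structureFormat(a$query)
  noVirtual <- data.frame(s = character(), p = character(), o = character(),
                          stringsAsFactors = FALSE)
  if (inv$procedure == "substructureSearch") {
    opts <- matchOptions(
      searchMode = if (is.null(a$searchMode)) "substructure" else a$searchMode,
      chargeMode = if (is.null(a$chargeMode)) "defaultChargeAsAny" else a$chargeMode,
      isotopeMode = if (is.null(a$isotopeMode)) "defaultIsotopeAsStandard" else a$isotopeMode,
      stereoMode = if (is.null(a$stereoMode)) "ignoreStereo" else a$stereoMode,
      tautomerMode = if (is.null(a$tautomerMode)) "ignoreTautomers" else a$tautomerMode)
    hits <- substructureSearch(index, a$query, fmt, opts, topn = a$topn)
    terms <- rdfIri(hits)
    rn <- inv$resultNode
    if (isVarTerm(rn) || isBlankTerm(rn)) {
      sol <- .unitSolutions(length(terms))
      sol[[rn]] <- terms
    } else {
      sol <- .unitSolutions(sum(terms == rn))
    }
    return(list(solutions = sol, virtual = noVirtual))
  }
  # similarity search: structured results
  cutoff <- if (is.null(a$cutoff)) 0.8 else a$cutoff
  hits <- similaritySearch(index, a$query, fmt, cutoff = cutoff,
                           topn = a$topn)
  k <- nrow(hits)
  bnodes <- if (k) rdfBlank(paste0(bnodePrefix, "_", seq_len(k)))
            else character()
  virtual <- if (k == 0L) noVirtual else data.frame(
    s = rep(bnodes, times = 2L),
    p = c(rep(vocab$compound, k), rep(vocab$score, k)),
    o = c(rdfIri(hits$compound),
          vapply(hits$score, function(x)
            rdfLiteral(.formatDouble(x), datatype = .xsd("double")), "")),
    stringsAsFactors = FALSE)
  rn <- inv$resultNode
  if (isVarTerm(rn) || isBlankTerm(rn)) {
    sol <- .unitSolutions(k)
    sol[[rn]] <- bnodes
  } else {
    .queryError("the subject of a similarity search must be a variable")
  }
  list(solutions = sol, virtual = virtual)
}

# -- filter evaluation --------------------------------------------------------

.fvErr <- list(type = "err")

.filterValue <- function(expr, row) {
  if (expr$op == "term") {
    tm <- expr$term
    if (isVarTerm(tm)) {
      v <- if (tm %in% names(row)) row[[tm]] else NA_character_
      if (is.na(v)) return(.fvErr)
      tm <- v
    }
    if (isLiteralTerm(tm)) {
      dt <- termDatatype(tm)
      if (!is.na(dt)) {
        if (dt == .xsd("boolean"))
          return(list(type = "bool", v = termValue(tm) == "true"))
        num <- .termNumeric(tm)
        if (!is.na(num)) return(list(type = "num", v = num))
        return(list(type = "str", v = termValue(tm)))
      }
      return(list(type = "str", v = termValue(tm)))
    }
    return(list(type = "node", v = tm))
  }
  if (expr$op == "!") {
    v <- .filterValue(expr$args[[1L]], row)
    b <- .ebv(v)
    if (is.na(b)) return(.fvErr)
    return(list(type = "bool", v = !b))
  }
  if (expr$op %in% c("&&", "||")) {
    l <- .ebv(.filterValue(expr$args[[1L]], row))
    r <- .ebv(.filterValue(expr$args[[2L]], row))
    v <- if (expr$op == "&&") {
      if (isFALSE(l) || isFALSE(r)) FALSE
      else if (is.na(l) || is.na(r)) NA else TRUE
    } else {
      if (isTRUE(l) || isTRUE(r)) TRUE
      else if (is.na(l) || is.na(r)) NA else FALSE
    }
    if (is.na(v)) return(.fvErr)
    return(list(type = "bool", v = v))
  }
  # comparison
  l <- .filterValue(expr$args[[1L]], row)
  r <- .filterValue(expr$args[[2L]], row)
  if (l$type == "err" || r$type == "err") return(.fvErr)
  op <- expr$op
  if (l$type == "num" && r$type == "num") {
    v <- switch(op, "=" = l$v == r$v, "!=" = l$v != r$v, "<" = l$v < r$v,
                "<=" = l$v <= r$v, ">" = l$v > r$v, ">=" = l$v >= r$v)
    return(list(type = "bool", v = v))
  }
  if (l$type == "str" && r$type == "str") {
    v <- switch(op, "=" = l$v == r$v, "!=" = l$v != r$v, "<" = l$v < r$v,
                "<=" = l$v <= r$v, ">" = l$v > r$v, ">=" = l$v >= r$v)
    return(list(type = "bool", v = v))
  }
  if (l$type == "bool" && r$type == "bool") {
    if (op %in% c("=", "!="))
      return(list(type = "bool", v = if (op == "=") l$v == r$v else l$v != r$v))
    return(.fvErr)
  }
  if (l$type == "node" && r$type == "node" && op %in% c("=", "!="))
    return(list(type = "bool", v = if (op == "=") l$v == r$v else l$v != r$v))
  .fvErr
}

# effective boolean value; NA = type error
.ebv <- function(val) {
  switch(val$type,
         bool = val$v,
         num = !is.na(val$v) && val$v != 0,
         str = nzchar(val$v),
         NA)
}

# -- the evaluator ------------------------------------------------------------

#' Evaluate a parsed SPARQL query
#'
#' Evaluates the query's basic graph pattern against an RDF graph, with the
#' procedure-call extension enabled by default: patterns carrying the
#' chemical-search predicates are executed against the compound index
#' first (their arguments are constants), and the residual patterns are
#' then joined in.  Filters use the value semantics of the supported
#' subset: a type error inside a filter removes the row.  `ORDER BY`,
#' `DISTINCT`, `OFFSET` and `LIMIT` are applied last; without `ORDER BY`
#' the row order is the deterministic join order.
#'
#' A query whose patterns use no chemical-search predicate evaluates
#' identically with the extension enabled or disabled.
#'
#' @param query a [SparqlQuery-class] (or a query string).
#' @param graph an [RdfGraph-class]; may be `NULL` for procedure-only
#'   queries.
#' @param index a [CompoundIndex-class], required when the query invokes a
#'   search procedure.
#' @param vocab vocabulary from [sachemVocabulary()].
#' @param procedures set to `FALSE` to disable the procedure-call
#'   extension.
#' @return a [ResultSet-class].
#' @export
evaluateQuery <- function(query, graph = NULL, index = NULL,
                          vocab = sachemVocabulary(), procedures = TRUE) {
  if (is.character(query)) query <- parseSparql(query)
  patterns <- query@patterns
  triples <- if (is.null(graph)) {
    data.frame(s = character(), p = character(), o = character(),
               stringsAsFactors = FALSE)
  } else graph@triples

  invocations <- list()
  residual <- patterns
  if (procedures) {
    det <- detectProcedures(patterns, vocab)
    invocations <- det$invocations
    residual <- det$residual
  }
  if (length(invocations) && is.null(index))
    .queryError("query invokes a chemical search but no compound index is configured")

  sol <- .unitSolutions(1L)
  virtualAll <- NULL
  for (k in seq_along(invocations)) {
    res <- runInvocation(invocations[[k]], index, vocab,
                         bnodePrefix = paste0("proc", k))
    sol <- .joinSolutions(sol, res$solutions)
    virtualAll <- rbind(virtualAll, res$virtual)
  }
  if (!is.null(virtualAll) && nrow(virtualAll))
    triples <- rbind(triples, virtualAll)

  if (nrow(residual)) {
    for (ri in seq_len(nrow(residual))) {
      sol <- .joinSolutions(sol, .matchPattern(residual[ri, ], triples))
      if (!nrow(sol) && ncol(sol) == 0L) sol <- sol[integer(0), , drop = FALSE]
    }
  }

  for (f in query@filters) {
    if (!nrow(sol)) break
    keep <- vapply(seq_len(nrow(sol)), function(i) {
      isTRUE(.ebv(.filterValue(f, as.list(sol[i, , drop = FALSE]))))
    }, logical(1))
    sol <- sol[keep, , drop = FALSE]
  }

  # projection
  varCols <- names(sol)[startsWith(names(sol), "?")]
  if (identical(query@variables, "*")) {
    projVars <- substring(varCols, 2L)
  } else {
    projVars <- query@variables
  }
  out <- .unitSolutions(nrow(sol))
  for (v in projVars) {
    cn <- paste0("?", v)
    out[[v]] <- if (cn %in% names(sol)) sol[[cn]]
                else rep(NA_character_, nrow(sol))
  }

  # solution modifiers
  if (nrow(query@orderBy)) {
    keys <- list()
    for (oi in rev(seq_len(nrow(query@orderBy)))) {
      v <- query@orderBy$var[oi]
      colv <- if (v %in% names(out)) out[[v]] else rep(NA_character_, nrow(out))
      nums <- vapply(colv, function(x)
        if (is.na(x)) NA_real_ else .termNumeric(x), numeric(1))
      key <- if (all(!is.na(nums) | is.na(colv))) nums else colv
      ord <- order(key, decreasing = query@orderBy$desc[oi],
                   method = "radix", na.last = !query@orderBy$desc[oi])
      out <- out[ord, , drop = FALSE]
    }
    rownames(out) <- NULL
  }
  if (query@distinct && nrow(out)) {
    out <- out[!duplicated(do.call(paste, c(as.list(out), sep = "\r"))), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.na(query@offset) && query@offset > 0L)
    out <- out[-seq_len(min(query@offset, nrow(out))), , drop = FALSE]
  if (!is.na(query@limit) && nrow(out) > query@limit)
    out <- out[seq_len(query@limit), , drop = FALSE]
  rownames(out) <- NULL

  new("ResultSet", variables = projVars, bindings = out)
}
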