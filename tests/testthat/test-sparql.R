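# SPARQL parsing, procedure-call detection, invocation execution and full
# query evaluation.

workedIndex <- function() {
  we <- workedExamples()
  buildIndex(data.frame(
    iri = paste0("http://example.org/compound/", names(we$molecules)),
    structure = unname(we$molecules), format = "smiles",
    stringsAsFactors = FALSE), name = "worked")
}

test_that("the SELECT subset parses into a deterministic plan", {
  q <- parseSparql("SELECT ?s WHERE { ?s ?p ?o }")
  expect_equal(q@variables, "s")
  expect_equal(nrow(q@patterns), 1L)

  q2 <- parseSparql(paste(
    "PREFIX ex: <http://example.org/>",
    "SELECT DISTINCT ?a ?b WHERE {",
    "  ?a ex:p ?b ; ex:q \"lit\" .",
    "  FILTER(?b > 3 && ?b <= 10)",
    "} ORDER BY DESC(?b) LIMIT 5 OFFSET 2", sep = "\n"))
  expect_true(q2@distinct)
  expect_equal(nrow(q2@patterns), 2L)
  expect_equal(length(q2@filters), 1L)
  expect_equal(q2@orderBy$var, "b")
  expect_true(q2@orderBy$desc)
  expect_equal(q2@limit, 5L)
  expect_equal(q2@offset, 2L)
})

test_that("blank-node argument shorthand expands to shared patterns", {
  we <- workedExamples()
  q <- parseSparql(we$queries[["substructure"]])
  # the procedure pattern plus two argument patterns share one fresh bnode
  expect_equal(nrow(q@patterns), 3L)
  bn <- q@patterns$o[grepl("substructureSearch", q@patterns$p)]
  expect_true(isBlankTerm(bn))
  expect_equal(sum(q@patterns$s == bn), 2L)
})

test_that("unsupported constructs raise named unsupported-feature errors", {
  expect_error(parseSparql("SELECT ?s WHERE { ?s ?p ?o . OPTIONAL { ?s ?q ?r } }"),
               class = "unsupportedFeature")
  expect_error(parseSparql("SELECT ?s WHERE { { ?s ?p ?o } UNION { ?s ?q ?r } }"),
               class = "unsupportedFeature")
  expect_error(parseSparql("CONSTRUCT { ?s ?p ?o } WHERE { ?s ?p ?o }"),
               class = "unsupportedFeature")
  expect_error(parseSparql("SELECT ?s WHERE { ?s ?p ?o FILTER(regex(?s, \"x\")) }"),
               class = "unsupportedFeature")
  expect_match(tryCatch(parseSparql("ASK { ?s ?p ?o }"),
                        error = conditionMessage), "ASK")
})

test_that("syntax errors carry line and column", {
  e <- tryCatch(parseSparql("SELECT ?s WHERE {\n ?s ?p }"),
                error = function(e) e)
  expect_s3_class(e, "sparqlSyntaxError")
  expect_match(conditionMessage(e), "line 2")
})

test_that("procedure detection separates invocations from residual patterns", {
  vocab <- sachemVocabulary()
  we <- workedExamples()
  q <- parseSparql(we$queries[["substructure"]])
  det <- detectProcedures(q@patterns, vocab)
  expect_length(det$invocations, 1L)
  expect_equal(nrow(det$residual), 0L)
  inv <- det$invocations[[1]]
  expect_equal(inv$procedure, "substructureSearch")
  expect_equal(inv$args$query, we$molecules[["adenine"]])
  expect_equal(inv$args$tautomerMode, "inchiTautomers")
  expect_equal(inv$resultNode, "?COMPOUND")

  # no chemical predicates: everything is residual
  q2 <- parseSparql("SELECT ?s WHERE { ?s ?p ?o . ?o ?q ?r }")
  det2 <- detectProcedures(q2@patterns, vocab)
  expect_length(det2$invocations, 0L)
  expect_equal(nrow(det2$residual), 2L)
})

test_that("malformed procedure calls are rejected", {
  vocab <- sachemVocabulary()
  base <- vocab$base
  mk <- function(body) parseSparql(paste0(
    "PREFIX sachem: <", base, ">\nSELECT ?c WHERE { ", body, " }"))
  # object is not a blank node
  q <- mk("?c sachem:substructureSearch <http://x/args>")
  expect_error(detectProcedures(q@patterns, vocab),
               class = "queryEvaluationError")
  # unknown argument property
  q2 <- mk("?c sachem:substructureSearch [ sachem:query \"CCO\" ; sachem:bogus 1 ]")
  expect_error(detectProcedures(q2@patterns, vocab),
               class = "queryEvaluationError")
  # missing mandatory query argument
  q3 <- mk("?c sachem:substructureSearch [ sachem:topn 5 ]")
  expect_error(detectProcedures(q3@patterns, vocab),
               class = "queryEvaluationError")
  # variable argument values are unsupported, not silently misread
  q4 <- mk("?c sachem:substructureSearch [ sachem:query ?q ]")
  expect_error(detectProcedures(q4@patterns, vocab),
               class = "unsupportedFeature")
})

test_that("substructure invocations bind compound IRIs directly", {
  idx <- buildIndex(data.frame(iri = c("http://x/D1", "http://x/D2", "http://x/D3"),
                               structure = c("CCO", "CC(=O)O", "c1ccccc1")))
  vocab <- sachemVocabulary()
  inv <- list(procedure = "substructureSearch", resultNode = "?C",
              args = list(query = "CO"), argNode = "_:a")
  res <- runInvocation(inv, idx, vocab)
  expect_equal(res$solutions[["?C"]], rdfIri(c("http://x/D1", "http://x/D2")))
  expect_equal(nrow(res$virtual), 0L)
})

test_that("similarity invocations produce structured blank-node results", {
  idx <- buildIndex(data.frame(iri = c("http://x/D1", "http://x/D2"),
                               structure = c("CCO", "c1ccccc1")))
  vocab <- sachemVocabulary()
  inv <- list(procedure = "similaritySearch", resultNode = "?HIT",
              args = list(query = "CCO", cutoff = 0), argNode = "_:a")
  res <- runInvocation(inv, idx, vocab)
  expect_equal(nrow(res$solutions), 2L)
  expect_true(all(isBlankTerm(res$solutions[["?HIT"]])))
  expect_equal(nrow(res$virtual), 4L)  # compound + score per hit
  expect_setequal(unique(res$virtual$p), c(vocab$compound, vocab$score))
  # empty hit lists still succeed
  inv0 <- list(procedure = "similaritySearch", resultNode = "?HIT",
               args = list(query = "CCO", cutoff = 1, topn = 0L),
               argNode = "_:a")
  res0 <- runInvocation(inv0, idx, vocab)
  expect_equal(nrow(res0$solutions), 0L)
})

test_that("plain BGP evaluation matches a brute-force enumeration", {
  checked <- 0L
  for (trial in 1:25) {
    g <- randomStore(25L + trial, seed = 1000L + trial)
    pats <- randomPatterns(sample(1:3, 1L), seed = 2000L + trial)
    vars <- unique(sub("^\\?", "",
                       unlist(pats)[startsWith(unlist(pats), "?")]))
    if (!length(vars)) next
    q <- new("SparqlQuery", variables = vars, distinct = FALSE,
             patterns = pats, filters = list(),
             orderBy = data.frame(var = character(), desc = logical()),
             limit = NA_integer_, offset = NA_integer_,
             prefixes = character())
    got <- resultSetKey(evaluateQuery(q, g))
    want <- solutionKey(bruteForceBgp(pats, rdfTriples(g)), vars)
    expect_equal(got, want)
    checked <- checked + 1L
  }
  expect_gt(checked, 15L)
})

test_that("the worked similarity query binds compound and score variables", {
  idx <- workedIndex()
  we <- workedExamples()
  rs <- evaluateQuery(parseSparql(we$queries[["similarity"]]), index = idx)
  b <- resultBindings(rs)
  expect_equal(resultVariables(rs), c("COMPOUND", "SCORE"))
  expect_true(nrow(b) >= 1L)
  expect_true(all(isIriTerm(b$COMPOUND)))
  expect_true(rdfIri("http://example.org/compound/adenine") %in% b$COMPOUND)
  scores <- as.numeric(vapply(b$SCORE, termValue, ""))
  expect_true(all(scores >= 0.5 & scores <= 1))
})

test_that("procedure results join with residual store patterns", {
  idx <- workedIndex()
  ttl <- c("@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
           "<http://example.org/compound/adenine> rdfs:label \"adenine\" .",
           "<http://example.org/compound/adenosine> rdfs:label \"adenosine\" .",
           "<http://example.org/compound/ethanol> rdfs:label \"ethanol\" .")
  g <- parseTurtle(ttl)
  q <- parseSparql(paste0(
    "PREFIX sachem: <", sachemVocabulary()$base, ">\n",
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>\n",
    "SELECT ?name WHERE {\n",
    "  ?c sachem:substructureSearch [ sachem:query \"Nc1ncnc2[nH]cnc12\" ;\n",
    "       sachem:tautomerMode sachem:inchiTautomers ] .\n",
    "  ?c rdfs:label ?name .\n",
    "} ORDER BY ?name"))
  rs <- evaluateQuery(q, graph = g, index = idx)
  expect_equal(resultBindings(rs)$name,
               c("\"adenine\"", "\"adenosine\""))
})

test_that("the bound IRI multiset equals the direct search output", {
  idx <- workedIndex()
  base <- sachemVocabulary()$base
  for (query in c("CO", "cc", "CCO", "N")) {
    q <- parseSparql(paste0(
      "PREFIX sachem: <", base, ">\n",
      "SELECT ?c WHERE { ?c sachem:substructureSearch [ sachem:query \"",
      query, "\" ] }"))
    rs <- evaluateQuery(q, index = idx)
    direct <- substructureSearch(idx, query)
    expect_equal(sort(unname(vapply(resultBindings(rs)$c, termValue, ""))),
                 sort(direct))
    expect_equal(nrow(resultBindings(rs)), length(direct))
  }
})

test_that("filters, ordering and slicing follow SPARQL semantics", {
  g <- parseTurtle(c("@prefix ex: <http://x/> .",
                     "ex:a ex:v 1 . ex:b ex:v 5 . ex:c ex:v 10 .",
                     "ex:d ex:w \"str\" ."))
  run <- function(text) resultBindings(evaluateQuery(parseSparql(text), g))
  expect_equal(nrow(run("PREFIX ex: <http://x/> SELECT ?s WHERE { ?s ex:v ?x . FILTER(?x >= 5) }")), 2L)
  # type errors inside FILTER remove the row, they do not fail the query
  expect_equal(nrow(run("PREFIX ex: <http://x/> SELECT ?s ?x WHERE { ?s ?p ?x . FILTER(?x > 2) }")), 2L)
  ordered <- run("PREFIX ex: <http://x/> SELECT ?s ?x WHERE { ?s ex:v ?x } ORDER BY DESC(?x)")
  expect_equal(ordered$s, rdfIri(c("http://x/c", "http://x/b", "http://x/a")))
  sliced <- run("PREFIX ex: <http://x/> SELECT ?s ?x WHERE { ?s ex:v ?x } ORDER BY ?x LIMIT 1 OFFSET 1")
  expect_equal(sliced$s, rdfIri("http://x/b"))
  expect_equal(nrow(run("PREFIX ex: <http://x/> SELECT ?s WHERE { ?s ex:v 5 }")), 1L)
})

test_that("queries without chemical predicates ignore the extension entirely", {
  g <- randomStore(40L, seed = 77L)
  idx <- workedIndex()
  queries <- c(
    "SELECT ?s WHERE { ?s ?p ?o }",
    "SELECT ?s ?o WHERE { ?s <http://x/p1> ?o . ?o <http://x/p2> ?z }",
    "SELECT * WHERE { ?s ?p \"v1\" }")
  for (text in queries) {
    q <- parseSparql(text)
    withExt <- evaluateQuery(q, g, index = idx, procedures = TRUE)
    withoutExt <- evaluateQuery(q, g, index = idx, procedures = FALSE)
    expect_identical(resultBindings(withExt), resultBindings(withoutExt))
  }
})
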