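# Result serialization in the four standard formats, the protocol handler,
# and an end-to-end check over a real HTTP socket.

sampleResultSet <- function() {
  new("ResultSet", variables = c("s", "n", "u"),
      bindings = data.frame(
        s = c(rdfIri("http://x/a"), rdfBlank("z9")),
        n = c(rdfLiteral("plain, \"quoted\""),
              rdfLiteral("0.5", datatype = "http://www.w3.org/2001/XMLSchema#double")),
        u = c(NA_character_, rdfLiteral("salut", lang = "fr")),
        stringsAsFactors = FALSE))
}

test_that("JSON serialization follows the W3C results layout", {
  rs <- new("ResultSet", variables = "s",
            bindings = data.frame(s = rdfIri("http://x/a"),
                                  stringsAsFactors = FALSE))
  doc <- jsonlite::fromJSON(rawToChar(serializeResults(rs, "json")),
                            simplifyVector = FALSE)
  expect_equal(doc$head$vars[[1]], "s")
  expect_equal(doc$results$bindings[[1]]$s,
               list(type = "uri", value = "http://x/a"))
})

test_that("CSV and TSV follow their format rules", {
  empty <- resultSet(c("a", "b"))
  expect_equal(rawToChar(serializeResults(empty, "csv")), "a,b\r\n")
  rs <- sampleResultSet()
  csv <- rawToChar(serializeResults(rs, "csv"))
  expect_match(csv, "\"plain, \"\"quoted\"\"\"", fixed = TRUE)
  tsv <- rawToChar(serializeResults(rs, "tsv"))
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(lines[1], "?s\t?n\t?u")
  # typed literal keeps full Turtle-like term syntax in TSV
  expect_match(lines[3],
               "\"0.5\"\\^\\^<http://www.w3.org/2001/XMLSchema#double>")
  # unbound variable: empty CSV/TSV field
  expect_equal(strsplit(lines[2], "\t")[[1]][3], NA_character_)
})

test_that("serialize then parse restores the result set (modulo bnode labels)", {
  rs <- sampleResultSet()
  for (f in c("json", "xml", "tsv")) {
    back <- parseResults(serializeResults(rs, f), f)
    expect_equal(resultVariables(back), resultVariables(rs))
    b1 <- resultBindings(rs); b2 <- resultBindings(back)
    expect_equal(nrow(b2), nrow(b1))
    for (v in resultVariables(rs)) {
      isB <- !is.na(b1[[v]]) & startsWith(b1[[v]], "_:")
      expect_equal(b2[[v]][!isB], b1[[v]][!isB])
      expect_true(all(startsWith(b2[[v]][isB], "_:")))
    }
  }
})

test_that("second-pass serialization is byte-stable in every format", {
  rs <- sampleResultSet()
  for (f in c("json", "xml", "csv", "tsv")) {
    b1 <- serializeResults(rs, f)
    p1 <- parseResults(b1, f)
    b2 <- serializeResults(p1, f)
    p2 <- parseResults(b2, f)
    b3 <- serializeResults(p2, f)
    expect_identical(b2, b3)
  }
})

test_that("malformed result documents are rejected", {
  expect_error(parseResults('{"results": {"bindings": []}}', "json"), "head")
  expect_error(serializeResults(sampleResultSet(), "yaml"), "unknown")
  # RFC 4180: a quoted comma stays one cell
  rs <- parseResults("a\r\n\"x,y\"\r\n", "csv")
  expect_equal(nrow(resultBindings(rs)), 1L)
  expect_equal(termValue(resultBindings(rs)$a[1]), "x,y")
})

appFixture <- function() {
  we <- workedExamples()
  idx <- buildIndex(data.frame(
    iri = paste0("http://example.org/compound/", names(we$molecules)),
    structure = unname(we$molecules), format = "smiles"))
  ttl <- paste0("<http://example.org/compound/", names(we$molecules),
                "> <http://example.org/prop/label> \"",
                names(we$molecules), "\" .")
  list(app = sparqlApp(list(demo = list(index = idx, graph = parseTurtle(ttl)))),
       idx = idx, we = we)
}

test_that("the protocol handler implements GET, POST and content negotiation", {
  fx <- appFixture()
  enc <- httpuv::encodeURIComponent
  q <- fx$we$queries[["substructure"]]
  get <- fx$app(list(PATH_INFO = "/sparql/endpoint/demo",
                     REQUEST_METHOD = "GET",
                     QUERY_STRING = paste0("?query=", enc(q)),
                     HTTP_ACCEPT = "text/csv"))
  expect_equal(get$status, 200L)
  expect_equal(get$headers[["Content-Type"]], "text/csv")
  expect_match(rawToChar(get$body), "adenosine")

  # POST with form body
  bodyIn <- paste0("query=", enc(q))
  post <- fx$app(list(PATH_INFO = "/sparql/endpoint/demo",
                      REQUEST_METHOD = "POST",
                      CONTENT_TYPE = "application/x-www-form-urlencoded",
                      rook.input = list(read = function() charToRaw(bodyIn))))
  expect_equal(post$status, 200L)
  expect_equal(post$headers[["Content-Type"]],
               "application/sparql-results+json")

  # POST with a raw sparql-query body and XML negotiation
  post2 <- fx$app(list(PATH_INFO = "/sparql/endpoint/demo",
                       REQUEST_METHOD = "POST",
                       CONTENT_TYPE = "application/sparql-query",
                       HTTP_ACCEPT = "application/sparql-results+xml",
                       rook.input = list(read = function() charToRaw(q))))
  expect_equal(post2$status, 200L)
  expect_match(rawToChar(post2$body), "<sparql")

  expect_equal(fx$app(list(PATH_INFO = "/sparql/endpoint/nope",
                           REQUEST_METHOD = "GET",
                           QUERY_STRING = ""))$status, 404L)
  bad <- fx$app(list(PATH_INFO = "/sparql/endpoint/demo",
                     REQUEST_METHOD = "GET",
                     QUERY_STRING = paste0("?query=", enc("SELECT ?x WHERE {"))))
  expect_equal(bad$status, 400L)
  unsup <- fx$app(list(PATH_INFO = "/sparql/endpoint/demo",
                       REQUEST_METHOD = "GET",
                       QUERY_STRING = paste0("?query=",
                         enc("SELECT ?s WHERE { ?s ?p ?o . OPTIONAL { ?s ?q ?r } }"))))
  expect_equal(unsup$status, 400L)
  expect_match(unsup$body, "OPTIONAL")
})

test_that("a generic HTTP client gets the same bindings as direct library calls", {
  port <- 18632L
  bg <- callr::r_bg(function(port) {
    library(ChemSparql)
    we <- workedExamples()
    idx <- buildIndex(data.frame(
      iri = paste0("http://example.org/compound/", names(we$molecules)),
      structure = unname(we$molecules), format = "smiles"))
    runEndpoint(list(demo = list(index = idx, graph = NULL)), port = port)
  }, args = list(port = port))
  on.exit(bg$kill())

  fetch <- function(query, accept) {
    url <- paste0("http://127.0.0.1:", port, "/sparql/endpoint/demo?query=",
                  curl::curl_escape(query))
    h <- curl::new_handle()
    curl::handle_setheaders(h, Accept = accept)
    for (attempt in 1:50) {
      res <- tryCatch(curl::curl_fetch_memory(url, handle = h),
                      error = function(e) NULL)
      if (!is.null(res)) return(res)
      Sys.sleep(0.2)
    }
    stop("endpoint did not come up")
  }

  fx <- appFixture()
  we <- fx$we
  direct <- substructureSearch(
    fx$idx, we$molecules[["adenine"]],
    opts = matchOptions(tautomerMode = "inchiTautomers"))
  for (f in c("json", "xml", "csv", "tsv")) {
    res <- fetch(we$queries[["substructure"]],
                 ChemSparql:::.resultMediaTypes[[f]])
    expect_equal(res$status_code, 200L)
    rs <- parseResults(res$content, f)
    got <- vapply(resultBindings(rs)$COMPOUND, termValue, "")
    expect_equal(sort(unname(got)), sort(direct))
  }
})
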