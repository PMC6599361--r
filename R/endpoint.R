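# SPARQL 1.1 protocol endpoint (query operation) over httpuv.  One route
# per dataset, mirroring the per-dataset endpoint layout
# /sparql/endpoint/<dataset>; result format chosen by Accept header.

.parseQueryString <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  pairs <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in pairs) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    key <- httpuv::decodeURIComponent(kv[1L])
    val <- if (length(kv) > 1L)
      httpuv::decodeURIComponent(chartr("+", " ", paste(kv[-1L], collapse = "=")))
    else ""
    out[[key]] <- val
  }
  out
}

# pick a result format from an Accept header value
.negotiateFormat <- function(accept, defaultFormat) {
  if (is.null(accept) || !nzchar(accept)) return(defaultFormat)
  for (part in strsplit(accept, ",", fixed = TRUE)[[1]]) {
    mt <- trimws(strsplit(part, ";", fixed = TRUE)[[1]][1L])
    if (mt == "*/*") return(defaultFormat)
    hit <- names(.resultMediaTypes)[.resultMediaTypes == mt]
    if (length(hit)) return(hit[1L])
    if (mt == "application/json") return("json")
    if (mt == "application/xml" || mt == "text/xml") return("xml")
  }
  defaultFormat
}

#' SPARQL protocol request handler
#'
#' Builds the Rook/httpuv application implementing the query operation of
#' the SPARQL 1.1 protocol: `GET` with a `query=` parameter, `POST` with an
#' URL-encoded form, or `POST` with an `application/sparql-query` body.
#' The path `/sparql/endpoint/<name>` selects the dataset; the Accept
#' header selects among the four result media types (default JSON).
#' Malformed or unsupported queries yield 400 with a plain-text message;
#' unknown datasets yield 404.
#'
#' @param datasets named list; each element a list with components `index`
#'   (a [CompoundIndex-class]) and optionally `graph` (an
#'   [RdfGraph-class]).
#' @param vocab vocabulary from [sachemVocabulary()].
#' @param defaultFormat format used when the client does not negotiate one.
#' @return a function `(req) -> response` suitable for
#'   [httpuv::startServer()] (and directly callable in tests).
#' @export
sparqlApp <- function(datasets, vocab = sachemVocabulary(),
                      defaultFormat = "json") {
  force(datasets); force(vocab); force(defaultFormat)
  function(req) {
    textResponse <- function(status, body)
      list(status = status,
           headers = list("Content-Type" = "text/plain; charset=utf-8"),
           body = body)
    path <- req$PATH_INFO
    m <- regmatches(path, regexec("^/sparql/endpoint/([^/]+)$", path))[[1]]
    if (length(m) != 2L)
      return(textResponse(404L, "not found"))
    name <- m[2L]
    ds <- datasets[[name]]
    if (is.null(ds))
      return(textResponse(404L, paste0("unknown dataset: ", name)))

    queryText <- NULL
    if (identical(req$REQUEST_METHOD, "GET")) {
      params <- .parseQueryString(req$QUERY_STRING)
      queryText <- params$query
    } else if (identical(req$REQUEST_METHOD, "POST")) {
      ctype <- req$CONTENT_TYPE
      if (is.null(ctype)) ctype <- ""
      body <- if (!is.null(req$rook.input)) {
        raw <- req$rook.input$read()
        if (length(raw)) rawToChar(raw) else ""
      } else ""
      if (grepl("application/sparql-query", ctype, fixed = TRUE)) {
        queryText <- body
      } else {
        params <- .parseQueryString(body)
        queryText <- params$query
      }
    } else {
      return(textResponse(405L, "method not allowed"))
    }
    if (is.null(queryText) || !nzchar(queryText))
      return(textResponse(400L, "missing query parameter"))

    accept <- req$HTTP_ACCEPT
    format <- .negotiateFormat(accept, defaultFormat)

    rs <- tryCatch(
      evaluateQuery(parseSparql(queryText), graph = ds$graph,
                    index = ds$index, vocab = vocab),
      sparqlSyntaxError = function(e) e,
      unsupportedFeature = function(e) e,
      queryEvaluationError = function(e) e)
    if (inherits(rs, "condition"))
      return(textResponse(400L, conditionMessage(rs)))

    body <- serializeResults(rs, format)
    list(status = 200L,
         headers = list("Content-Type" = .resultMediaTypes[[format]]),
         body = body)
  }
}

#' Start / stop the HTTP endpoint
#'
#' Runs the SPARQL endpoint on a background httpuv server.  The returned
#' handle must be passed to `stopEndpoint()` (or
#' `httpuv::stopServer()`) when done.
#'
#' @inheritParams sparqlApp
#' @param host interface to bind.
#' @param port TCP port.
#' @return `startEndpoint()` returns the httpuv server handle.
#' @export
startEndpoint <- function(datasets, port = 8080L, host = "127.0.0.1",
                          vocab = sachemVocabulary(), defaultFormat = "json") {
  app <- sparqlApp(datasets, vocab, defaultFormat)
  httpuv::startServer(host, port, list(call = app))
}

#' @rdname startEndpoint
#' @param server handle returned by `startEndpoint()`.
#' @export
stopEndpoint <- function(server) {
  httpuv::stopServer(server)
  invisible(NULL)
}

#' @rdname startEndpoint
#' @details `runEndpoint()` blocks the R process serving requests until
#'   interrupted; it is what the command-line `serve` subcommand uses.
#' @export
runEndpoint <- function(datasets, port = 8080L, host = "127.0.0.1",
                        vocab = sachemVocabulary(), defaultFormat = "json") {
  server <- startEndpoint(datasets, port, host, vocab, defaultFormat)
  on.exit(httpuv::stopServer(server))
  message(sprintf("SPARQL endpoint listening on http://%s:%d/sparql/endpoint/<dataset>",
                  host, port))
  message("datasets: ", paste(names(datasets), collapse = ", "))
  while (TRUE) {
    httpuv::service(250)
  }
}
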