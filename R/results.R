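# The four standard SPARQL query result serializations (XML, JSON, CSV,
# TSV) and their inverses for round-trip testing.  Blank nodes get stable
# per-response labels (b0, b1, ... in order of first occurrence).  CSV
# carries plain lexical forms and thus loses the term kind, as the CSV
# rules prescribe; TSV keeps the full term syntax.

.resultMediaTypes <- c(json = "application/sparql-results+json",
                       xml = "application/sparql-results+xml",
                       csv = "text/csv",
                       tsv = "text/tab-separated-values")

# relabel blank nodes in first-occurrence order
.relabelBnodes <- function(bindings) {
  if (!nrow(bindings) || !ncol(bindings)) return(bindings)
  map <- character()
  for (i in seq_len(nrow(bindings))) {
    for (j in seq_len(ncol(bindings))) {
      v <- bindings[i, j]
      if (!is.na(v) && isBlankTerm(v) && !(v %in% names(map)))
        map[v] <- rdfBlank(paste0("b", length(map)))
    }
  }
  if (!length(map)) return(bindings)
  for (j in seq_len(ncol(bindings))) {
    col <- bindings[[j]]
    hit <- !is.na(col) & col %in% names(map)
    col[hit] <- map[col[hit]]
    bindings[[j]] <- col
  }
  bindings
}

.termToJsonObj <- function(term) {
  if (isIriTerm(term))
    return(list(type = "uri", value = termValue(term)))
  if (isBlankTerm(term))
    return(list(type = "bnode", value = termValue(term)))
  obj <- list(type = "literal", value = termValue(term))
  dt <- termDatatype(term)
  lg <- termLang(term)
  if (!is.na(dt)) obj$datatype <- dt
  if (!is.na(lg)) obj[["xml:lang"]] <- lg
  obj
}

.jsonObjToTerm <- function(obj) {
  switch(obj$type,
         uri = rdfIri(obj$value),
         bnode = rdfBlank(obj$value),
         literal = ,
         "typed-literal" = rdfLiteral(obj$value, datatype = obj$datatype,
                                      lang = obj[["xml:lang"]]),
         stop("unknown term type in JSON results: ", obj$type))
}

.csvQuote <- function(x) {
  need <- grepl("[\",\r\n]", x)
  x[need] <- paste0("\"", gsub("\"", "\"\"", x[need]), "\"")
  x
}

.csvPlain <- function(term) {
  if (is.na(term)) return("")
  termValue(term)
}

.tsvTerm <- function(term) {
  if (is.na(term)) return("")
  term  # the internal encoding is already Turtle-like term syntax
}

#' Serialize a result set
#'
#' Writes a [ResultSet-class] in one of the four standard SPARQL query
#' result formats: `json` (head/vars and results/bindings objects), `xml`
#' (the sparql/head/results document), `csv` (plain lexical forms with
#' RFC 4180 quoting and CRLF row endings) and `tsv` (full Turtle-like term
#' syntax).  Unbound variables become an omitted binding (JSON, XML) or an
#' empty field (CSV, TSV).  Blank node labels are rewritten to stable
#' per-response labels.
#'
#' @param rs a [ResultSet-class].
#' @param format one of `"xml"`, `"json"`, `"csv"`, `"tsv"`.
#' @return the serialized document as a raw vector (UTF-8 bytes).
#' @export
serializeResults <- function(rs, format = c("json", "xml", "csv", "tsv")) {
  if (!format[1L] %in% c("json", "xml", "csv", "tsv"))
    stop("unknown result format: ", format[1L])
  format <- match.arg(format)
  vars <- rs@variables
  bindings <- .relabelBnodes(rs@bindings)
  n <- nrow(bindings)

  text <- switch(format,
    json = {
      rows <- lapply(seq_len(n), function(i) {
        row <- list()
        for (v in vars) {
          tm <- bindings[[v]][i]
          if (!is.na(tm)) row[[v]] <- .termToJsonObj(tm)
        }
        row
      })
      doc <- list(head = list(vars = vars), results = list(bindings = rows))
      jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = FALSE)
    },
    xml = {
      doc <- xml2::xml_new_root("sparql",
                                xmlns = "http://www.w3.org/2005/sparql-results#")
      head <- xml2::xml_add_child(doc, "head")
      for (v in vars) xml2::xml_add_child(head, "variable", name = v)
      results <- xml2::xml_add_child(doc, "results")
      for (i in seq_len(n)) {
        res <- xml2::xml_add_child(results, "result")
        for (v in vars) {
          tm <- bindings[[v]][i]
          if (is.na(tm)) next
          bnd <- xml2::xml_add_child(res, "binding", name = v)
          if (isIriTerm(tm)) {
            xml2::xml_add_child(bnd, "uri", termValue(tm))
          } else if (isBlankTerm(tm)) {
            xml2::xml_add_child(bnd, "bnode", termValue(tm))
          } else {
            dt <- termDatatype(tm); lg <- termLang(tm)
            lit <- xml2::xml_add_child(bnd, "literal", termValue(tm))
            if (!is.na(dt)) xml2::xml_set_attr(lit, "datatype", dt)
            if (!is.na(lg)) xml2::xml_set_attr(lit, "xml:lang", lg)
          }
        }
      }
      as.character(doc)
    },
    csv = {
      header <- paste(.csvQuote(vars), collapse = ",")
      rows <- vapply(seq_len(n), function(i) {
        paste(.csvQuote(vapply(vars, function(v)
          .csvPlain(bindings[[v]][i]), "")), collapse = ",")
      }, "")
      paste0(paste(c(header, rows), collapse = "\r\n"), "\r\n")
    },
    tsv = {
      header <- paste(paste0("?", vars), collapse = "\t")
      rows <- vapply(seq_len(n), function(i) {
        paste(vapply(vars, function(v) .tsvTerm(bindings[[v]][i]), ""),
              collapse = "\t")
      }, "")
      paste0(paste(c(header, rows), collapse = "\n"), "\n")
    })
  charToRaw(enc2utf8(as.character(text)))
}

# RFC 4180 line splitter: fields may contain quoted commas and newlines
.parseCsvText <- function(text) {
  chars <- strsplit(text, "")[[1]]
  rows <- list(); field <- ""; row <- character(); inq <- FALSE
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (inq) {
      if (ch == "\"") {
        if (i < n && chars[i + 1L] == "\"") { field <- paste0(field, "\""); i <- i + 2L; next }
        inq <- FALSE; i <- i + 1L; next
      }
      field <- paste0(field, ch); i <- i + 1L; next
    }
    if (ch == "\"") { inq <- TRUE; i <- i + 1L; next }
    if (ch == ",") { row <- c(row, field); field <- ""; i <- i + 1L; next }
    if (ch == "\r" || ch == "\n") {
      if (ch == "\r" && i < n && chars[i + 1L] == "\n") i <- i + 1L
      rows[[length(rows) + 1L]] <- c(row, field)
      row <- character(); field <- ""
      i <- i + 1L
      next
    }
    field <- paste0(field, ch); i <- i + 1L
  }
  if (nzchar(field) || length(row))
    rows[[length(rows) + 1L]] <- c(row, field)
  rows
}

# parse a Turtle-like TSV cell back into an encoded term
.parseTsvTerm <- function(cell) {
  if (!nzchar(cell)) return(NA_character_)
  if (startsWith(cell, "<") || startsWith(cell, "_:")) return(cell)
  if (startsWith(cell, "\"")) return(cell)
  if (grepl("^[+-]?[0-9]", cell)) {
    dt <- if (grepl("[eE]", cell)) .xsd("double")
          else if (grepl("\\.", cell)) .xsd("decimal") else .xsd("integer")
    return(rdfLiteral(cell, datatype = dt))
  }
  if (cell %in% c("true", "false"))
    return(rdfLiteral(cell, datatype = .xsd("boolean")))
  stop("malformed TSV term: ", cell)
}

#' Parse a serialized result set
#'
#' Inverse of [serializeResults()] up to blank-node relabeling.  CSV is
#' lossy by design: every non-empty cell becomes a plain literal and empty
#' cells become unbound variables, so a CSV round trip preserves bytes but
#' not term kinds.
#'
#' @param bytes raw vector or character scalar holding the document.
#' @param format one of `"xml"`, `"json"`, `"csv"`, `"tsv"`.
#' @return a [ResultSet-class].
#' @export
parseResults <- function(bytes, format = c("json", "xml", "csv", "tsv")) {
  format <- match.arg(format)
  text <- if (is.raw(bytes)) rawToChar(bytes) else bytes
  Encoding(text) <- "UTF-8"
  if (format == "json") {
    doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    if (is.null(doc$head) || is.null(doc$head$vars))
      stop("malformed JSON results: missing head")
    vars <- as.character(unlist(doc$head$vars))
    rows <- doc$results$bindings
    bindings <- .unitSolutions(length(rows))
    for (v in vars)
      bindings[[v]] <- vapply(rows, function(r)
        if (!is.null(r[[v]])) .jsonObjToTerm(r[[v]]) else NA_character_, "")
    return(new("ResultSet", variables = vars, bindings = bindings))
  }
  if (format == "xml") {
    doc <- xml2::read_xml(text)
    ns <- c(sr = "http://www.w3.org/2005/sparql-results#")
    vars <- xml2::xml_attr(
      xml2::xml_find_all(doc, ".//sr:head/sr:variable", ns), "name")
    results <- xml2::xml_find_all(doc, ".//sr:results/sr:result", ns)
    bindings <- .unitSolutions(length(results))
    cols <- lapply(vars, function(v) rep(NA_character_, length(results)))
    names(cols) <- vars
    for (i in seq_along(results)) {
      for (bnd in xml2::xml_find_all(results[[i]], "./sr:binding", ns)) {
        v <- xml2::xml_attr(bnd, "name")
        child <- xml2::xml_child(bnd)
        kind <- xml2::xml_name(child)
        val <- xml2::xml_text(child)
        cols[[v]][i] <- switch(kind,
          uri = rdfIri(val),
          bnode = rdfBlank(val),
          literal = {
            dt <- xml2::xml_attr(child, "datatype")
            lg <- xml2::xml_attr(child, "lang")
            rdfLiteral(val,
                       datatype = if (!is.na(dt)) dt else NULL,
                       lang = if (!is.na(lg)) lg else NULL)
          },
          stop("malformed XML results: unknown binding child ", kind))
      }
    }
    for (v in vars) bindings[[v]] <- cols[[v]]
    return(new("ResultSet", variables = vars, bindings = bindings))
  }
  if (format == "csv") {
    rows <- .parseCsvText(text)
    if (!length(rows)) stop("malformed CSV results: no header")
    vars <- rows[[1L]]
    body <- rows[-1L]
    bindings <- .unitSolutions(length(body))
    for (j in seq_along(vars)) {
      bindings[[vars[j]]] <- vapply(body, function(r) {
        cell <- if (j <= length(r)) r[j] else ""
        if (nzchar(cell)) rdfLiteral(cell) else NA_character_
      }, "")
    }
    return(new("ResultSet", variables = vars, bindings = bindings))
  }
  # tsv
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) stop("malformed TSV results: no header")
  vars <- sub("^\\?", "", strsplit(lines[1L], "\t", fixed = TRUE)[[1]])
  body <- lines[-1L]
  body <- body[nzchar(body) | seq_along(body) < length(body)]
  bindings <- .unitSolutions(length(body))
  cols <- lapply(vars, function(v) rep(NA_character_, length(body)))
  names(cols) <- vars
  for (i in seq_along(body)) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    for (j in seq_along(vars)) {
      cell <- if (j <= length(cells)) cells[j] else ""
      cols[[vars[j]]][i] <- .parseTsvTerm(cell)
    }
  }
  for (v in vars) bindings[[v]] <- cols[[v]]
  new("ResultSet", variables = vars, bindings = bindings)
}
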