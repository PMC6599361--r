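# SPARQL SELECT parser for the supported subset: PREFIX, SELECT (vars or *,
# DISTINCT), WHERE with triple patterns (';', ',', '[]' abbreviations),
# FILTER with comparisons and &&/||/!, ORDER BY, LIMIT, OFFSET.
# Unsupported SPARQL constructs raise an explicit unsupported-feature error
# naming the construct.

.sparqlSyntaxError <- function(line, col, msg) {
  stop(structure(class = c("sparqlSyntaxError", "parseError", "error",
                           "condition"),
                 list(message = sprintf("SPARQL syntax error at line %d, column %d: %s",
                                        line, col, msg), call = NULL)))
}

.unsupportedFeature <- function(what) {
  stop(structure(class = c("unsupportedFeature", "error", "condition"),
                 list(message = paste0("unsupported SPARQL feature: ", what),
                      call = NULL)))
}

.sparqlKeywords <- c("PREFIX", "SELECT", "WHERE", "FILTER", "ORDER", "BY",
                     "ASC", "DESC", "LIMIT", "OFFSET", "DISTINCT", "TRUE",
                     "FALSE", "A", "BASE")
.unsupportedKeywords <- c("OPTIONAL", "UNION", "SERVICE", "GRAPH", "MINUS",
                          "BIND", "VALUES", "EXISTS", "CONSTRUCT", "ASK",
                          "DESCRIBE", "INSERT", "DELETE", "REDUCED", "FROM",
                          "NAMED", "GROUP", "HAVING", "WITH", "UNDEF")

.sparqlTokens <- function(text) {
  lines <- strsplit(text, "\r?\n")[[1]]
  if (!length(lines)) lines <- ""
  toks <- list()
  push <- function(type, txt, line, col)
    toks[[length(toks) + 1L]] <<- list(type = type, text = txt,
                                       line = line, col = col)
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      rest <- substring(s, i)
      if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
      if (ch == "#") break
      m <- function(re) {
        r <- regmatches(rest, regexpr(re, rest, perl = TRUE))
        if (length(r) && nzchar(r)) r else NULL
      }
      if (ch == "<") {
        t <- m("^<[^<>\"{}|^`\\\\[:space:]]*>")
        if (!is.null(t)) { push("iri", t, ln, i); i <- i + nchar(t); next }
        t <- m("^<=|^<")
        push("op", t, ln, i); i <- i + nchar(t); next
      }
      if (ch %in% c("?", "$")) {
        t <- m("^[?$][A-Za-z_][A-Za-z0-9_]*")
        if (is.null(t)) .sparqlSyntaxError(ln, i, "malformed variable name")
        push("var", paste0("?", substring(t, 2L)), ln, i)
        i <- i + nchar(t); next
      }
      if (ch == "\"" || ch == "'") {
        qre <- if (ch == "\"") "^\"(?:[^\"\\\\]|\\\\.)*\""
               else "^'(?:[^'\\\\]|\\\\.)*'"
        t <- m(qre)
        if (is.null(t)) .sparqlSyntaxError(ln, i, "unterminated string literal")
        push("string", t, ln, i); i <- i + nchar(t)
        rest2 <- substring(s, i)
        lt <- regmatches(rest2, regexpr("^@[A-Za-z][A-Za-z0-9-]*", rest2))
        if (length(lt) && nzchar(lt)) {
          push("langtag", lt, ln, i); i <- i + nchar(lt)
        } else if (startsWith(rest2, "^^")) {
          push("dtsep", "^^", ln, i); i <- i + 2L
        }
        next
      }
      if (startsWith(rest, "_:")) {
        t <- m("^_:[A-Za-z0-9][A-Za-z0-9_.-]*")
        if (is.null(t)) .sparqlSyntaxError(ln, i, "malformed blank node label")
        push("bnode", t, ln, i); i <- i + nchar(t); next
      }
      t <- m("^&&|^\\|\\||^!=|^>=|^<=|^=|^>|^!")
      if (!is.null(t)) { push("op", t, ln, i); i <- i + nchar(t); next }
      t <- m("^[+-]?[0-9]+\\.[0-9]+(?:[eE][+-]?[0-9]+)?|^[+-]?[0-9]+(?:[eE][+-]?[0-9]+)?")
      if (!is.null(t)) { push("number", t, ln, i); i <- i + nchar(t); next }
      t <- m("^[A-Za-z_][A-Za-z0-9_]*(?=[[:space:]]*\\()")
      # a bare identifier followed by '(' outside keyword position is a
      # built-in call; checked later against the keyword list
      t <- m("^([A-Za-z][A-Za-z0-9_.-]*)?:([A-Za-z0-9_][A-Za-z0-9_.%-]*)?")
      if (!is.null(t) && grepl(":", t)) {
        while (endsWith(t, ".")) t <- substr(t, 1L, nchar(t) - 1L)
        push("pname", t, ln, i); i <- i + nchar(t); next
      }
      t <- m("^[A-Za-z_][A-Za-z0-9_]*")
      if (!is.null(t)) {
        kw <- toupper(t)
        if (kw %in% .unsupportedKeywords) .unsupportedFeature(kw)
        push("word", t, ln, i); i <- i + nchar(t); next
      }
      if (ch %in% c("{", "}", "(", ")", "[", "]", ";", ",", ".", "*")) {
        push(ch, ch, ln, i); i <- i + 1L; next
      }
      if (ch %in% c("/", "|", "^", "+")) .unsupportedFeature("property paths")
      .sparqlSyntaxError(ln, i, paste0("unexpected character '", ch, "'"))
    }
  }
  toks
}

#' Parse a SPARQL SELECT query
#'
#' Parses the supported SPARQL subset into a deterministic query plan.
#' Anonymous blank nodes (`[ p o ; ... ]`) expand into fresh blank-node
#' labeled triple patterns.  Unsupported SPARQL constructs (OPTIONAL,
#' UNION, SERVICE, property paths, CONSTRUCT/ASK/DESCRIBE, aggregates,
#' built-in calls) raise an unsupported-feature error naming the construct;
#' malformed input raises a syntax error with line and column.
#'
#' @param text the query string.
#' @return a [SparqlQuery-class].
#' @examples
#' parseSparql("SELECT ?s WHERE { ?s ?p ?o }")
#' @export
parseSparql <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .sparqlTokens(text)
  pos <- 1L
  prefixes <- character()
  patterns <- list()
  filters <- list()
  bnodeN <- 0L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { tk <- toks[[pos]]; pos <<- pos + 1L; tk }
  atWord <- function(w) {
    tk <- peek()
    !is.null(tk) && tk$type == "word" && toupper(tk$text) == w
  }
  expectType <- function(type, what = type) {
    tk <- peek()
    if (is.null(tk)) {
      last <- if (length(toks)) toks[[length(toks)]] else list(line = 1L, col = 1L)
      .sparqlSyntaxError(last$line, last$col, paste0("expected ", what,
                                                     " but reached end of query"))
    }
    if (tk$type != type)
      .sparqlSyntaxError(tk$line, tk$col,
                         paste0("expected ", what, ", found '", tk$text, "'"))
    advance()
  }
  fail <- function(msg) {
    tk <- peek()
    if (is.null(tk)) {
      last <- if (length(toks)) toks[[length(toks)]] else list(line = 1L, col = 1L)
      .sparqlSyntaxError(last$line, last$col, msg)
    }
    .sparqlSyntaxError(tk$line, tk$col, msg)
  }
  freshBnode <- function() {
    bnodeN <<- bnodeN + 1L
    rdfBlank(paste0("q", bnodeN))
  }
  expandPname <- function(tk) {
    i <- regexpr(":", tk$text, fixed = TRUE)
    pfx <- substr(tk$text, 1L, i - 1L)
    if (pfx == "") pfx <- "(default)"
    local <- substring(tk$text, i + 1L)
    if (!(pfx %in% names(prefixes)))
      .sparqlSyntaxError(tk$line, tk$col,
                         paste0("undefined prefix '", sub("\\(default\\)", "", pfx), ":'"))
    rdfIri(paste0(prefixes[[pfx]], local))
  }
  emit <- function(s, p, o)
    patterns[[length(patterns) + 1L]] <<- c(s, p, o)

  parseGraphTerm <- function(allowLiteral = TRUE, predicatePosition = FALSE) {
    tk <- peek()
    if (is.null(tk)) fail("unexpected end of query")
    if (tk$type == "var") { advance(); return(tk$text) }
    if (tk$type == "iri") {
      advance(); return(tk$text)
    }
    if (tk$type == "pname") { advance(); return(expandPname(tk)) }
    if (tk$type == "word" && toupper(tk$text) == "A" && predicatePosition) {
      advance()
      return(rdfIri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"))
    }
    if (predicatePosition) fail("expected predicate")
    if (tk$type == "bnode") { advance(); return(tk$text) }
    if (tk$type == "[") return(parseBlankNodePropertyList())
    if (!allowLiteral) fail("expected subject term")
    if (tk$type == "string") {
      advance()
      value <- .unescapeLiteral(substr(tk$text, 2L, nchar(tk$text) - 1L))
      nx <- peek()
      if (!is.null(nx) && nx$type == "langtag") {
        advance(); return(rdfLiteral(value, lang = substring(nx$text, 2L)))
      }
      if (!is.null(nx) && nx$type == "dtsep") {
        advance()
        dtk <- peek()
        if (is.null(dtk) || !(dtk$type %in% c("iri", "pname")))
          fail("expected datatype IRI after '^^'")
        dt <- parseGraphTerm(allowLiteral = FALSE)
        return(rdfLiteral(value, datatype = termValue(dt)))
      }
      return(rdfLiteral(value))
    }
    if (tk$type == "number") {
      advance()
      dt <- if (grepl("[eE]", tk$text)) .xsd("double")
            else if (grepl("\\.", tk$text)) .xsd("decimal") else .xsd("integer")
      return(rdfLiteral(tk$text, datatype = dt))
    }
    if (tk$type == "word" && toupper(tk$text) %in% c("TRUE", "FALSE")) {
      advance()
      return(rdfLiteral(tolower(tk$text), datatype = .xsd("boolean")))
    }
    fail(paste0("unexpected token '", tk$text, "'"))
  }

  parseBlankNodePropertyList <- function() {
    expectType("[")
    node <- freshBnode()
    tk <- peek()
    if (!is.null(tk) && tk$type != "]") parsePredicateObjectList(node)
    expectType("]")
    node
  }

  parsePredicateObjectList <- function(subject) {
    repeat {
      pred <- parseGraphTerm(predicatePosition = TRUE)
      repeat {
        obj <- parseGraphTerm()
        emit(subject, pred, obj)
        nx <- peek()
        if (!is.null(nx) && nx$type == ",") { advance(); next }
        break
      }
      nx <- peek()
      if (!is.null(nx) && nx$type == ";") {
        advance()
        nx2 <- peek()
        if (!is.null(nx2) &&
            (nx2$type %in% c("iri", "pname", "var") ||
             (nx2$type == "word" && toupper(nx2$text) == "A"))) next
      }
      break
    }
  }

  # -- filter expressions -----------------------------------------------------
  parsePrimary <- function() {
    tk <- peek()
    if (is.null(tk)) fail("unexpected end of filter expression")
    if (tk$type == "op" && tk$text == "!") {
      advance()
      return(list(op = "!", args = list(parsePrimary())))
    }
    if (tk$type == "(") {
      advance()
      e <- parseOr()
      expectType(")")
      return(e)
    }
    if (tk$type == "word" && !(toupper(tk$text) %in% c("TRUE", "FALSE"))) {
      nx <- if (pos + 1L <= length(toks)) toks[[pos + 1L]] else NULL
      if (!is.null(nx) && nx$type == "(")
        .unsupportedFeature(paste0("built-in call ", toupper(tk$text), "()"))
      fail(paste0("unexpected identifier '", tk$text, "' in filter"))
    }
    list(op = "term", term = parseGraphTerm())
  }
  parseRelational <- function() {
    left <- parsePrimary()
    tk <- peek()
    if (!is.null(tk) && tk$type == "op" &&
        tk$text %in% c("=", "!=", "<", "<=", ">", ">=")) {
      advance()
      right <- parsePrimary()
      return(list(op = tk$text, args = list(left, right)))
    }
    left
  }
  parseAnd <- function() {
    left <- parseRelational()
    repeat {
      tk <- peek()
      if (!is.null(tk) && tk$type == "op" && tk$text == "&&") {
        advance()
        left <- list(op = "&&", args = list(left, parseRelational()))
      } else return(left)
    }
  }
  parseOr <- function() {
    left <- parseAnd()
    repeat {
      tk <- peek()
      if (!is.null(tk) && tk$type == "op" && tk$text == "||") {
        advance()
        left <- list(op = "||", args = list(left, parseAnd()))
      } else return(left)
    }
  }

  # -- prologue ---------------------------------------------------------------
  repeat {
    if (atWord("PREFIX")) {
      advance()
      pnTok <- expectType("pname", "prefix name")
      iriTok <- expectType("iri", "prefix IRI")
      pfx <- sub(":.*$", "", pnTok$text)
      if (pfx == "") pfx <- "(default)"
      prefixes[[pfx]] <- substr(iriTok$text, 2L, nchar(iriTok$text) - 1L)
    } else if (atWord("BASE")) {
      .unsupportedFeature("BASE")
    } else break
  }

  if (!atWord("SELECT")) fail("expected SELECT")
  advance()
  distinct <- FALSE
  if (atWord("DISTINCT")) { advance(); distinct <- TRUE }
  vars <- character()
  tk <- peek()
  if (!is.null(tk) && tk$type == "*") {
    advance()
    vars <- "*"
  } else {
    repeat {
      tk <- peek()
      if (!is.null(tk) && tk$type == "var") {
        advance()
        vars <- c(vars, substring(tk$text, 2L))
      } else break
    }
    if (!length(vars)) fail("expected projected variables or *")
  }

  if (atWord("WHERE")) advance()
  expectType("{", "'{' opening the graph pattern")
  repeat {
    tk <- peek()
    if (is.null(tk)) fail("unterminated graph pattern (missing '}')")
    if (tk$type == "}") { advance(); break }
    if (tk$type == "word" && toupper(tk$text) == "FILTER") {
      advance()
      expectType("(", "'(' after FILTER")
      filters[[length(filters) + 1L]] <- parseOr()
      expectType(")")
      next
    }
    if (tk$type == "{") .unsupportedFeature("nested group graph pattern")
    subject <- parseGraphTerm(allowLiteral = FALSE)
    parsePredicateObjectList(subject)
    nx <- peek()
    if (!is.null(nx) && nx$type == ".") advance()
  }

  orderBy <- data.frame(var = character(), desc = logical(),
                        stringsAsFactors = FALSE)
  if (atWord("ORDER")) {
    advance()
    if (!atWord("BY")) fail("expected BY after ORDER")
    advance()
    repeat {
      tk <- peek()
      if (is.null(tk)) break
      if (tk$type == "var") {
        advance()
        orderBy <- rbind(orderBy, data.frame(var = substring(tk$text, 2L),
                                             desc = FALSE))
      } else if (tk$type == "word" && toupper(tk$text) %in% c("ASC", "DESC")) {
        dir <- toupper(tk$text) == "DESC"
        advance()
        expectType("(")
        vtk <- expectType("var", "variable")
        expectType(")")
        orderBy <- rbind(orderBy, data.frame(var = substring(vtk$text, 2L),
                                             desc = dir))
      } else break
    }
    if (!nrow(orderBy)) fail("expected ordering condition after ORDER BY")
  }

  limit <- NA_integer_; offset <- NA_integer_
  repeat {
    if (atWord("LIMIT")) {
      advance()
      ntk <- expectType("number", "integer")
      limit <- as.integer(ntk$text)
    } else if (atWord("OFFSET")) {
      advance()
      ntk <- expectType("number", "integer")
      offset <- as.integer(ntk$text)
    } else break
  }

  tk <- peek()
  if (!is.null(tk))
    .sparqlSyntaxError(tk$line, tk$col,
                       paste0("unexpected trailing token '", tk$text, "'"))

  patDf <- if (length(patterns)) {
    data.frame(s = vapply(patterns, `[`, "", 1L),
               p = vapply(patterns, `[`, "", 2L),
               o = vapply(patterns, `[`, "", 3L), stringsAsFactors = FALSE)
  } else {
    data.frame(s = character(), p = character(), o = character(),
               stringsAsFactors = FALSE)
  }

  new("SparqlQuery", variables = vars, distinct = distinct,
      patterns = patDf, filters = filters, orderBy = orderBy,
      limit = limit, offset = offset, prefixes = prefixes)
}
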