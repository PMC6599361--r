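# Minimal RDF term model plus Turtle / N-Triples readers for the subset the
# service consumes: prefixed names, IRIs, literals (plain, typed, language
# tagged, numeric and boolean shorthand), blank nodes and the ';' ',' '[]'
# abbreviations.

.xsd <- function(local) paste0("http://www.w3.org/2001/XMLSchema#", local)

#' RDF term encoding
#'
#' Terms are encoded as single character strings in an N-Triples-like
#' syntax: IRIs as `<iri>`, literals as `"lexical"` with an optional
#' `@lang` or `^^<datatype>` suffix, blank nodes as `_:label` and (inside
#' query patterns) variables as `?name`.  These helpers build and inspect
#' encoded terms.
#'
#' @param iri,label,name plain strings.
#' @param value literal lexical form (unescaped).
#' @param datatype optional datatype IRI.
#' @param lang optional language tag (mutually exclusive with `datatype`).
#' @return `rdfIri()`, `rdfLiteral()` and `rdfBlank()` return encoded terms;
#'   the predicates return logicals; `termValue()` returns the IRI, label
#'   or lexical form; `termDatatype()`/`termLang()` return `NA` when absent.
#' @export
rdfIri <- function(iri) {
  if (!length(iri)) return(character())
  paste0("<", iri, ">")
}

#' @rdname rdfIri
#' @export
rdfBlank <- function(label) {
  if (!length(label)) return(character())
  paste0("_:", label)
}

.escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescapeLiteral <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    s <- x[k]
    res <- ""
    i <- 1L
    while (i <= nchar(s)) {
      ch <- substr(s, i, i)
      if (ch == "\\" && i < nchar(s)) {
        nx <- substr(s, i + 1L, i + 1L)
        res <- paste0(res, switch(nx, n = "\n", r = "\r", t = "\t",
                                  "\"" = "\"", "\\" = "\\", "'" = "'", nx))
        i <- i + 2L
      } else {
        res <- paste0(res, ch)
        i <- i + 1L
      }
    }
    out[k] <- res
  }
  out
}

#' @rdname rdfIri
#' @export
rdfLiteral <- function(value, datatype = NULL, lang = NULL) {
  if (!is.null(datatype) && !is.null(lang))
    stop("a literal cannot have both a datatype and a language tag")
  if (!length(value)) return(character())
  base <- paste0("\"", .escapeLiteral(as.character(value)), "\"")
  if (!is.null(lang)) return(paste0(base, "@", lang))
  if (!is.null(datatype)) return(paste0(base, "^^<", datatype, ">"))
  base
}

#' @rdname rdfIri
#' @param term an encoded term.
#' @export
isIriTerm <- function(term) startsWith(term, "<")

#' @rdname rdfIri
#' @export
isLiteralTerm <- function(term) startsWith(term, "\"")

#' @rdname rdfIri
#' @export
isBlankTerm <- function(term) startsWith(term, "_:")

#' @rdname rdfIri
#' @export
isVarTerm <- function(term) startsWith(term, "?")

#' @rdname rdfIri
#' @export
termValue <- function(term) {
  if (isIriTerm(term)) return(substr(term, 2L, nchar(term) - 1L))
  if (isBlankTerm(term)) return(substr(term, 3L, nchar(term)))
  if (isVarTerm(term)) return(substr(term, 2L, nchar(term)))
  if (isLiteralTerm(term)) {
    # find closing quote of the lexical part (skip escapes)
    chars <- strsplit(term, "")[[1]]
    i <- 2L
    while (i <= length(chars)) {
      if (chars[i] == "\\") { i <- i + 2L; next }
      if (chars[i] == "\"") break
      i <- i + 1L
    }
    return(.unescapeLiteral(substr(term, 2L, i - 1L)))
  }
  term
}

.literalSuffix <- function(term) {
  chars <- strsplit(term, "")[[1]]
  i <- 2L
  while (i <= length(chars)) {
    if (chars[i] == "\\") { i <- i + 2L; next }
    if (chars[i] == "\"") break
    i <- i + 1L
  }
  substr(term, i + 1L, nchar(term))
}

#' @rdname rdfIri
#' @export
termDatatype <- function(term) {
  if (!isLiteralTerm(term)) return(NA_character_)
  suf <- .literalSuffix(term)
  if (startsWith(suf, "^^<")) substr(suf, 4L, nchar(suf) - 1L)
  else NA_character_
}

#' @rdname rdfIri
#' @export
termLang <- function(term) {
  if (!isLiteralTerm(term)) return(NA_character_)
  suf <- .literalSuffix(term)
  if (startsWith(suf, "@")) substr(suf, 2L, nchar(suf)) else NA_character_
}

# numeric value of a literal term, NA when not numeric
.termNumeric <- function(term) {
  if (!isLiteralTerm(term)) return(NA_real_)
  dt <- termDatatype(term)
  numTypes <- .xsd(c("integer", "decimal", "double", "float", "int", "long",
                     "nonNegativeInteger", "positiveInteger"))
  if (!is.na(dt) && !(dt %in% numTypes)) return(NA_real_)
  v <- suppressWarnings(as.numeric(termValue(term)))
  if (is.na(dt) && is.na(v)) return(NA_real_)
  v
}

# -- Turtle / N-Triples parsing ----------------------------------------------

.turtleError <- function(line, msg) {
  stop(structure(class = c("turtleParseError", "parseError", "error",
                           "condition"),
                 list(message = sprintf("Turtle parse error (line %d): %s",
                                        line, msg), call = NULL)))
}

# tokenize turtle text; returns data.frame(type, text, line)
.turtleTokens <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  toks <- list()
  push <- function(type, txt, line)
    toks[[length(toks) + 1L]] <<- list(type = type, text = txt, line = line)
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
        if (is.null(t)) .turtleError(ln, "malformed IRI")
        push("iri", t, ln); i <- i + nchar(t); next
      }
      if (ch == "\"" || ch == "'") {
        qre <- if (ch == "\"") "^\"(?:[^\"\\\\]|\\\\.)*\""
               else "^'(?:[^'\\\\]|\\\\.)*'"
        t <- m(qre)
        if (is.null(t)) .turtleError(ln, "unterminated string literal")
        push("string", t, ln); i <- i + nchar(t)
        rest2 <- substring(s, i)
        lt <- regmatches(rest2, regexpr("^@[A-Za-z][A-Za-z0-9-]*", rest2))
        if (length(lt) && nzchar(lt)) {
          push("langtag", lt, ln); i <- i + nchar(lt)
        } else if (startsWith(rest2, "^^")) {
          push("dtsep", "^^", ln); i <- i + 2L
        }
        next
      }
      if (startsWith(rest, "@prefix") || startsWith(rest, "@base")) {
        t <- m("^@[a-z]+")
        push("directive", t, ln); i <- i + nchar(t); next
      }
      t <- m("^(PREFIX|BASE)\\b")
      if (!is.null(t) && grepl("^(PREFIX|BASE)", rest)) {
        push("directive", paste0("@", tolower(t)), ln); i <- i + nchar(t); next
      }
      if (startsWith(rest, "_:")) {
        t <- m("^_:[A-Za-z0-9][A-Za-z0-9_.-]*")
        if (is.null(t)) .turtleError(ln, "malformed blank node label")
        push("bnode", t, ln); i <- i + nchar(t); next
      }
      t <- m("^[+-]?[0-9]+\\.[0-9]+[eE][+-]?[0-9]+|^[+-]?[0-9]+[eE][+-]?[0-9]+|^[+-]?[0-9]+\\.[0-9]+|^[+-]?[0-9]+")
      if (!is.null(t)) { push("number", t, ln); i <- i + nchar(t); next }
      if (grepl("^(true|false)\\b", rest)) {
        t <- m("^(true|false)")
        push("boolean", t, ln); i <- i + nchar(t); next
      }
      if (grepl("^a[[:space:]<]", paste0(rest, " "))) {
        push("a", "a", ln); i <- i + 1L; next
      }
      # pname: prefix:local, prefix: alone, or :local
      t <- {
        r <- regmatches(rest, regexpr("^([A-Za-z][A-Za-z0-9_.-]*)?:([A-Za-z0-9_][A-Za-z0-9_.%-]*)?", rest, perl = TRUE))
        if (length(r) && nzchar(r) && grepl(":", r)) r else NULL
      }
      if (!is.null(t)) {
        while (endsWith(t, ".")) t <- substr(t, 1L, nchar(t) - 1L)
        push("pname", t, ln); i <- i + nchar(t); next
      }
      if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
        push(ch, ch, ln); i <- i + 1L; next
      }
      .turtleError(ln, paste0("unexpected character '", ch, "'"))
    }
  }
  if (!length(toks))
    return(data.frame(type = character(), text = character(),
                      line = integer(), stringsAsFactors = FALSE))
  data.frame(type = vapply(toks, `[[`, "", "type"),
             text = vapply(toks, `[[`, "", "text"),
             line = vapply(toks, function(x) as.integer(x$line), 1L),
             stringsAsFactors = FALSE)
}

#' Parse Turtle text into an RDF graph
#'
#' Supports the Turtle subset used by the service: `@prefix`/`PREFIX`
#' directives, IRIs, prefixed names, `a`, string literals with language
#' tags or datatypes, numeric and boolean shorthand, blank node labels and
#' anonymous `[ ... ]` blank nodes, and the `;`/`,` abbreviations.
#'
#' @param text Turtle content (single string or character vector of lines),
#'   or a path to a file.
#' @return an [RdfGraph-class].
#' @export
parseTurtle <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readChar(text, file.size(text), useBytes = TRUE)
  toks <- .turtleTokens(text)
  pos <- 1L
  prefixes <- c(xsd = .xsd(""))
  triples <- list()
  bnodeN <- 0L

  peek <- function() if (pos <= nrow(toks)) toks[pos, ] else NULL
  advance <- function() { tk <- toks[pos, ]; pos <<- pos + 1L; tk }
  expect <- function(type) {
    tk <- peek()
    if (is.null(tk) || tk$type != type)
      .turtleError(if (is.null(tk)) max(toks$line, 1L) else tk$line,
                   paste0("expected '", type, "'"))
    advance()
  }
  emit <- function(s, p, o)
    triples[[length(triples) + 1L]] <<- c(s, p, o)
  freshBnode <- function() {
    bnodeN <<- bnodeN + 1L
    rdfBlank(paste0("g", bnodeN))
  }
  expandPname <- function(txt, line) {
    i <- regexpr(":", txt, fixed = TRUE)
    pfx <- substr(txt, 1L, i - 1L)
    if (pfx == "") pfx <- "(default)"
    local <- substring(txt, i + 1L)
    if (!(pfx %in% names(prefixes)))
      .turtleError(line, paste0("undefined prefix '", pfx, ":'"))
    rdfIri(paste0(prefixes[[pfx]], local))
  }
  parseTermToken <- function() {
    tk <- peek()
    if (is.null(tk)) .turtleError(max(toks$line, 1L), "unexpected end of input")
    if (tk$type == "iri") {
      advance(); return(rdfIri(substr(tk$text, 2L, nchar(tk$text) - 1L)))
    }
    if (tk$type == "pname") { advance(); return(expandPname(tk$text, tk$line)) }
    if (tk$type == "bnode") { advance(); return(tk$text) }
    if (tk$type == "a") {
      advance()
      return(rdfIri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"))
    }
    if (tk$type == "string") {
      advance()
      raw <- substr(tk$text, 2L, nchar(tk$text) - 1L)
      value <- .unescapeLiteral(raw)
      nx <- peek()
      if (!is.null(nx) && nx$type == "langtag") {
        advance()
        return(rdfLiteral(value, lang = substring(nx$text, 2L)))
      }
      if (!is.null(nx) && nx$type == "dtsep") {
        advance()
        dtTok <- peek()
        if (is.null(dtTok) || !(dtTok$type %in% c("iri", "pname")))
          .turtleError(tk$line, "expected datatype IRI after '^^'")
        dt <- parseTermToken()
        return(rdfLiteral(value, datatype = termValue(dt)))
      }
      return(rdfLiteral(value))
    }
    if (tk$type == "number") {
      advance()
      dt <- if (grepl("[eE]", tk$text)) .xsd("double")
            else if (grepl("\\.", tk$text)) .xsd("decimal")
            else .xsd("integer")
      return(rdfLiteral(tk$text, datatype = dt))
    }
    if (tk$type == "boolean") {
      advance()
      return(rdfLiteral(tk$text, datatype = .xsd("boolean")))
    }
    if (tk$type == "[") return(parseBlankNodePropertyList())
    .turtleError(tk$line, paste0("unexpected token '", tk$text, "'"))
  }
  parseBlankNodePropertyList <- function() {
    expect("[")
    node <- freshBnode()
    tk <- peek()
    if (!is.null(tk) && tk$type != "]") parsePredicateObjectList(node)
    expect("]")
    node
  }
  parsePredicateObjectList <- function(subject) {
    repeat {
      tk <- peek()
      if (is.null(tk) || !(tk$type %in% c("iri", "pname", "a")))
        .turtleError(if (is.null(tk)) max(toks$line, 1L) else tk$line,
                     "expected predicate")
      pred <- parseTermToken()
      repeat {
        obj <- parseTermToken()
        emit(subject, pred, obj)
        nx <- peek()
        if (!is.null(nx) && nx$type == ",") { advance(); next }
        break
      }
      nx <- peek()
      if (!is.null(nx) && nx$type == ";") {
        advance()
        nx2 <- peek()
        if (!is.null(nx2) && nx2$type %in% c("iri", "pname", "a")) next
      }
      break
    }
  }

  while (!is.null(peek())) {
    tk <- peek()
    if (tk$type == "directive") {
      advance()
      if (tk$text == "@prefix") {
        pnTok <- expect("pname")
        iriTok <- expect("iri")
        pfx <- sub(":.*$", "", pnTok$text)
        if (pfx == "") pfx <- "(default)"
        prefixes[[pfx]] <- substr(iriTok$text, 2L, nchar(iriTok$text) - 1L)
        nx <- peek()
        if (!is.null(nx) && nx$type == ".") advance()
      } else {
        iriTok <- expect("iri")
        nx <- peek()
        if (!is.null(nx) && nx$type == ".") advance()
      }
      next
    }
    subject <- parseTermToken()
    parsePredicateObjectList(subject)
    expect(".")
  }

  tri <- if (length(triples)) {
    data.frame(s = vapply(triples, `[`, "", 1L),
               p = vapply(triples, `[`, "", 2L),
               o = vapply(triples, `[`, "", 3L), stringsAsFactors = FALSE)
  } else {
    data.frame(s = character(), p = character(), o = character(),
               stringsAsFactors = FALSE)
  }
  rdfGraph(tri)
}

#' Parse N-Triples text into an RDF graph
#'
#' N-Triples is a line-oriented subset of Turtle; this reader accepts plain
#' `<s> <p> <o> .` statements with IRI, blank node and literal terms.
#'
#' @inheritParams parseTurtle
#' @return an [RdfGraph-class].
#' @export
parseNTriples <- function(text) parseTurtle(text)

#' Serialize an RDF graph to N-Triples lines
#'
#' @param graph an [RdfGraph-class].
#' @return character vector of N-Triples statements (valid Turtle).
#' @export
writeNTriples <- function(graph) {
  tri <- graph@triples
  if (!nrow(tri)) return(character())
  paste(tri$s, tri$p, tri$o, ".")
}
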