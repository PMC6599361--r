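# Independent brute-force BGP evaluator: choose one store triple per
# pattern (cartesian), keep consistent assignments.  Used to cross-check
# the join-based evaluator on small stores.

bruteForceBgp <- function(patterns, triples) {
  isV <- function(x) startsWith(x, "?") | startsWith(x, "_:")
  nPat <- nrow(patterns)
  if (nPat == 0L) return(list(list()))
  perPattern <- vector("list", nPat)
  for (k in seq_len(nPat)) {
    cand <- list()
    for (ti in seq_len(nrow(triples))) {
      b <- list()
      ok <- TRUE
      for (slot in c("s", "p", "o")) {
        pv <- patterns[[slot]][k]
        tv <- triples[[slot]][ti]
        if (isV(pv)) {
          if (!is.null(b[[pv]]) && b[[pv]] != tv) { ok <- FALSE; break }
          b[[pv]] <- tv
        } else if (pv != tv) { ok <- FALSE; break }
      }
      if (ok) cand[[length(cand) + 1L]] <- b
    }
    if (!length(cand)) return(list())
    perPattern[[k]] <- cand
  }
  # cartesian combination with consistency filtering
  sols <- list(list())
  for (k in seq_len(nPat)) {
    nxt <- list()
    for (s in sols) {
      for (b in perPattern[[k]]) {
        merged <- s
        ok <- TRUE
        for (v in names(b)) {
          if (!is.null(merged[[v]]) && merged[[v]] != b[[v]]) { ok <- FALSE; break }
          merged[[v]] <- b[[v]]
        }
        if (ok) nxt[[length(nxt) + 1L]] <- merged
      }
    }
    sols <- nxt
    if (!length(sols)) return(list())
  }
  sols
}

# canonical multiset of solutions projected to ?-variables, for comparison
solutionKey <- function(sols, vars) {
  keys <- vapply(sols, function(s) {
    paste(vapply(vars, function(v) {
      x <- s[[paste0("?", v)]]
      if (is.null(x) || is.na(x)) "" else x
    }, ""), collapse = "\t")
  }, "")
  sort(keys)
}

resultSetKey <- function(rs) {
  b <- resultBindings(rs)
  if (!nrow(b)) return(character())
  vals <- lapply(resultVariables(rs), function(v) {
    x <- b[[v]]
    ifelse(is.na(x), "", x)
  })
  sort(do.call(paste, c(vals, sep = "\t")))
}

# deterministic random store over a small vocabulary
randomStore <- function(nTriples, seed) {
  withr::with_seed(seed, {
    subs <- rdfIri(paste0("http://x/s", 1:6))
    preds <- rdfIri(paste0("http://x/p", 1:4))
    objs <- c(rdfIri(paste0("http://x/s", 1:6)),
              paste0("\"v", 1:4, "\""))
    df <- unique(data.frame(s = sample(subs, nTriples, TRUE),
                            p = sample(preds, nTriples, TRUE),
                            o = sample(objs, nTriples, TRUE),
                            stringsAsFactors = FALSE))
    rdfGraph(df)
  })
}

randomPatterns <- function(nPat, seed) {
  withr::with_seed(seed, {
    vars <- c("?a", "?b", "?c", "?d")
    subs <- c(rdfIri(paste0("http://x/s", 1:6)), vars)
    preds <- c(rdfIri(paste0("http://x/p", 1:4)), vars)
    objs <- c(rdfIri(paste0("http://x/s", 1:6)),
              paste0("\"v", 1:4, "\""), vars)
    data.frame(s = sample(subs, nPat, TRUE),
               p = sample(preds, nPat, TRUE),
               o = sample(objs, nPat, TRUE), stringsAsFactors = FALSE)
  })
}
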