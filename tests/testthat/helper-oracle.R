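# Independent brute-force subgraph-isomorphism oracle.  Written from the
# mode semantics directly, with naive candidate enumeration in atom-index
# order; shares no code with the package's matcher.

oracleAtomOk <- function(qa, qi, ta, ti, opts) {
  if (qa$element[qi] != ta$element[ti]) return(FALSE)
  if (qa$aromatic[qi] != ta$aromatic[ti]) return(FALSE)
  cm <- opts@chargeMode
  if (cm == "defaultChargeAsAny") {
    if (qa$chargeSpecified[qi] && qa$charge[qi] != ta$charge[ti]) return(FALSE)
  } else if (cm == "defaultChargeAsZero") {
    qc <- if (qa$chargeSpecified[qi]) qa$charge[qi] else 0L
    if (qc != ta$charge[ti]) return(FALSE)
  }
  im <- opts@isotopeMode
  if (im == "defaultIsotopeAsStandard") {
    qv <- qa$isotope[qi]; tv <- ta$isotope[ti]
    if (is.na(qv) != is.na(tv)) return(FALSE)
    if (!is.na(qv) && qv != tv) return(FALSE)
  } else if (im == "defaultIsotopeAsAny") {
    if (qa$isotopeSpecified[qi]) {
      if (is.na(ta$isotope[ti]) || qa$isotope[qi] != ta$isotope[ti])
        return(FALSE)
    }
  }
  if (opts@searchMode == "exact") {
    if (!is.na(qa$totalH[qi]) && !is.na(ta$totalH[ti]) &&
        qa$totalH[qi] != ta$totalH[ti]) return(FALSE)
  } else if (!is.na(qa$explicitH[qi])) {
    if (qa$aromatic[qi] && qa$element[qi] == "N" && isTRUE(qa$inRing[qi]) &&
        opts@tautomerMode == "ignoreTautomers") {
      if (qa$explicitH[qi] != ta$totalH[ti]) return(FALSE)
    } else if (!is.na(ta$totalH[ti]) && qa$explicitH[qi] > ta$totalH[ti])
      return(FALSE)
  }
  TRUE
}

# sign of a permutation by explicit transposition counting (selection sort)
oraclePermSign <- function(perm) {
  perm <- as.integer(perm)
  swaps <- 0L
  for (i in seq_along(perm)) {
    while (perm[i] != i) {
      j <- perm[i]
      tmp <- perm[j]; perm[j] <- perm[i]; perm[i] <- tmp
      swaps <- swaps + 1L
    }
  }
  if (swaps %% 2L == 0L) 1L else -1L
}

oracleStereoOk <- function(q, t, map) {
  qa <- atoms(q); ta <- atoms(t)
  qb <- bonds(q); tb <- bonds(t)
  for (i in seq_len(nrow(qa))) {
    if (is.na(qa$parity[i])) next
    ti <- map[i]
    if (is.na(ta$parity[ti])) next
    qord <- q@tetraOrder[[i]]; tord <- t@tetraOrder[[ti]]
    if (is.null(qord) || is.null(tord)) next
    if (length(qord) == 3L) qord <- c(qord, 0L)
    if (length(tord) == 3L) tord <- c(tord, 0L)
    mq <- qord
    mq[qord != 0L] <- map[qord[qord != 0L]]
    if (any(mq == 0L) && !(0L %in% tord)) {
      rest <- setdiff(tord, mq)
      if (length(rest) != 1L) next
      mq[mq == 0L] <- rest
    }
    if (!setequal(mq, tord)) next
    sgn <- oraclePermSign(match(mq, tord))
    sameParity <- qa$parity[i] == ta$parity[ti]
    if ((sgn == 1L) != sameParity) return(FALSE)
  }
  for (bi in seq_len(nrow(qb))) {
    if (is.na(qb$config[bi])) next
    e1 <- map[qb$a1[bi]]; e2 <- map[qb$a2[bi]]
    tbi <- which((tb$a1 == e1 & tb$a2 == e2) | (tb$a1 == e2 & tb$a2 == e1))
    if (!length(tbi)) next
    tbi <- tbi[1L]
    if (is.na(tb$config[tbi])) next
    # side of a substituent x at double-bond end e: +1 on the reference
    # substituent's side, -1 on the other
    side <- function(x, e, ref) {
      if (x == ref) return(1L)
      nbrs <- unique(c(tb$a2[tb$a1 == e], tb$a1[tb$a2 == e]))
      nbrs <- setdiff(nbrs, c(e1, e2))
      if (x %in% nbrs) return(-1L)
      NA_integer_
    }
    ref1 <- if (tb$a1[tbi] == e1) tb$refA[tbi] else tb$refB[tbi]
    ref2 <- if (tb$a1[tbi] == e1) tb$refB[tbi] else tb$refA[tbi]
    s1 <- side(map[qb$refA[bi]], e1, ref1)
    s2 <- side(map[qb$refB[bi]], e2, ref2)
    if (is.na(s1) || is.na(s2)) next
    # target config relates its own refs; flip once per swapped side
    rel <- if (tb$config[tbi] == "cis") 1L else -1L
    relMapped <- rel * s1 * s2
    qRel <- if (qb$config[bi] == "cis") 1L else -1L
    if (qRel != relMapped) return(FALSE)
  }
  TRUE
}

# exhaustive backtracking over injective assignments in plain index order
oracleMatches <- function(query, target, opts = matchOptions()) {
  q <- normalizeAromaticity(query)
  t <- normalizeAromaticity(target)
  qa <- atoms(q); ta <- atoms(t)
  qb <- bonds(q); tb <- bonds(t)
  nq <- nrow(qa); nt <- nrow(ta)
  exact <- opts@searchMode == "exact"
  if (nq > nt) return(FALSE)
  if (exact && (nq != nt || nrow(qb) != nrow(tb))) return(FALSE)
  tBond <- matrix(NA_character_, nt, nt)
  for (bi in seq_len(nrow(tb))) {
    tBond[tb$a1[bi], tb$a2[bi]] <- tb$order[bi]
    tBond[tb$a2[bi], tb$a1[bi]] <- tb$order[bi]
  }
  map <- integer(nq)
  used <- logical(nt)
  recurse <- function(k) {
    if (k > nq) {
      if (exact) {
        # every target bond must be covered by a query bond
        covered <- 0L
        for (bi in seq_len(nrow(qb)))
          if (!is.na(tBond[map[qb$a1[bi]], map[qb$a2[bi]]])) covered <- covered + 1L
        if (covered != nrow(tb)) return(FALSE)
      }
      if (opts@stereoMode == "strictStereo" && !oracleStereoOk(q, t, map))
        return(FALSE)
      return(TRUE)
    }
    for (tj in seq_len(nt)) {
      if (used[tj]) next
      if (!oracleAtomOk(qa, k, ta, tj, opts)) next
      ok <- TRUE
      for (bi in seq_len(nrow(qb))) {
        other <- if (qb$a1[bi] == k) qb$a2[bi]
                 else if (qb$a2[bi] == k) qb$a1[bi] else next
        if (other < k) {
          o <- tBond[tj, map[other]]
          if (is.na(o) || o != qb$order[bi]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      map[k] <<- tj; used[tj] <<- TRUE
      if (recurse(k + 1L)) return(TRUE)
      used[tj] <<- FALSE
    }
    FALSE
  }
  recurse(1L)
}

# the full mode grid exercised by the oracle-equivalence checks:
# charge x isotope x stereo x search (tautomer handling stays at its
# default, which the oracle implements)
modeGrid <- function() {
  g <- expand.grid(chargeMode = c("defaultChargeAsAny", "defaultChargeAsZero",
                                  "ignoreCharges"),
                   isotopeMode = c("defaultIsotopeAsStandard",
                                   "defaultIsotopeAsAny", "ignoreIsotopes"),
                   stereoMode = c("strictStereo", "ignoreStereo"),
                   searchMode = c("substructure", "exact"),
                   stringsAsFactors = FALSE)
  g
}
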