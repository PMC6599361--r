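# Substructure / exact matching: VF2-style backtracking search with
# mode-dependent atom compatibility, post-mapping stereo validation and a
# pluggable tautomer canonicalizer.

#' Atom compatibility under the matching modes
#'
#' Decides whether a query atom may map onto a target atom: element symbols
#' and aromatic flags must agree, and the charge, isotope and hydrogen rules
#' of the selected modes must pass.  Unspecified query charges are wildcards
#' under `defaultChargeAsAny`, match only uncharged atoms under
#' `defaultChargeAsZero`, and `ignoreCharges` skips the comparison; the
#' isotope modes behave analogously with `defaultIsotopeAsStandard` reading
#' an unlabeled atom as the standard isotope.  A written query H count must
#' not exceed the target's hydrogen count (must equal it in exact mode); an
#' aromatic ring-nitrogen H count (`[nH]`) is enforced exactly under
#' `ignoreTautomers`, which is what pins a tautomer's mobile hydrogen in
#' place unless tautomer matching is requested.
#'
#' @param q,t single atom rows (as returned by `atoms(mol)[i, ]` on a
#'   normalized molecule, including the `totalH` and `inRing` columns).
#' @param opts a [MatchOptions-class].
#' @return `TRUE` when the atoms are compatible.
#' @export
atomCompatible <- function(q, t, opts = matchOptions()) {
  if (q$element != t$element || q$aromatic != t$aromatic) return(FALSE)
  ok <- switch(opts@chargeMode,
    ignoreCharges = TRUE,
    defaultChargeAsAny = !q$chargeSpecified || q$charge == t$charge,
    defaultChargeAsZero = (if (q$chargeSpecified) q$charge else 0L) == t$charge)
  if (!ok) return(FALSE)
  qi <- q$isotope; ti <- t$isotope
  ok <- switch(opts@isotopeMode,
    ignoreIsotopes = TRUE,
    defaultIsotopeAsAny = !q$isotopeSpecified ||
      (!is.na(ti) && qi == ti),
    defaultIsotopeAsStandard =
      (is.na(qi) && is.na(ti)) || (!is.na(qi) && !is.na(ti) && qi == ti))
  if (!ok) return(FALSE)
  if (opts@searchMode == "exact") {
    if (!is.na(q$totalH) && !is.na(t$totalH) && q$totalH != t$totalH)
      return(FALSE)
  } else if (!is.na(q$explicitH) && !is.na(t$totalH)) {
    strictNH <- q$aromatic && q$element == "N" && isTRUE(q$inRing) &&
      opts@tautomerMode == "ignoreTautomers"
    if (strictNH) {
      if (q$explicitH != t$totalH) return(FALSE)
    } else if (q$explicitH > t$totalH) return(FALSE)
  }
  TRUE
}

#' Bond compatibility
#'
#' Bonds are compatible when their order classes are equal.  Aromaticity
#' normalization has already merged kekulized rings into the aromatic class,
#' and the tautomer canonicalizer merges mobile-hydrogen ring bonds into the
#' tautomeric class, so a plain equality is the whole rule.
#'
#' @param qb,tb single bond rows (`bonds(mol)[i, ]`) or order-class strings.
#' @return `TRUE` when compatible.
#' @export
bondCompatible <- function(qb, tb) {
  qo <- if (is.data.frame(qb)) qb$order else qb
  to <- if (is.data.frame(tb)) tb$order else tb
  qo == to
}

# -- tautomer canonicalizer registry ------------------------------------------

.tautomerState <- new.env(parent = emptyenv())

#' Pluggable tautomer canonicalizer
#'
#' Tautomer-aware matching (`tautomerMode = "inchiTautomers"`) passes both
#' structures through a canonicalizer before the subgraph search.  The
#' default plug-in implements a bounded mobile-hydrogen relaxation: in every
#' ring system that contains nitrogen or oxygen, hydrogen placements on ring
#' N/O atoms are dropped and ring bond orders (single, double or aromatic)
#' are unified into one tautomeric order class.  This reproduces
#' tautomer-insensitive matching for heteroaromatic systems such as the
#' purine ring, without implementing the full InChI mobile-H algorithm.
#' `setTautomerCanonicalizer(NULL)` unregisters the plug-in, after which
#' requesting `inchiTautomers` raises an unsupported-feature error.
#'
#' @param fn a function `Molecule -> Molecule`, or `NULL` to unregister.
#' @return previous canonicalizer, invisibly.
#' @export
setTautomerCanonicalizer <- function(fn) {
  old <- .tautomerState$fn
  .tautomerState$fn <- fn
  invisible(old)
}

#' @rdname setTautomerCanonicalizer
#' @param mol a normalized [Molecule-class].
#' @export
mobileHCanonical <- function(mol) {
  mol <- .ensureNormalized(mol)
  a <- mol@atoms
  b <- mol@bonds
  if (!any(b$inRing)) return(mol)
  # ring systems = connected components over ring bonds
  comp <- seq_len(nrow(a))
  repeat {
    changed <- FALSE
    for (bi in which(b$inRing)) {
      m <- min(comp[b$a1[bi]], comp[b$a2[bi]])
      if (comp[b$a1[bi]] != m || comp[b$a2[bi]] != m) {
        comp[comp == comp[b$a1[bi]]] <- m
        comp[comp == comp[b$a2[bi]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ringAtoms <- unique(c(b$a1[b$inRing], b$a2[b$inRing]))
  for (cid in unique(comp[ringAtoms])) {
    members <- intersect(which(comp == cid), ringAtoms)
    if (!any(a$element[members] %in% c("N", "O"))) next
    no <- members[a$element[members] %in% c("N", "O")]
    a$explicitH[no] <- NA_integer_
    a$totalH[no] <- NA_integer_
    ringB <- which(b$inRing & b$a1 %in% members & b$a2 %in% members &
                     b$order %in% c("single", "double", "aromatic"))
    b$order[ringB] <- "tautomeric"
    b$config[ringB] <- NA_character_
  }
  new("Molecule", atoms = a, bonds = b, tetraOrder = mol@tetraOrder,
      source = mol@source)
}

.tautomerState$fn <- mobileHCanonical

.applyTautomerMode <- function(mol, opts) {
  if (opts@tautomerMode != "inchiTautomers") return(.ensureNormalized(mol))
  fn <- .tautomerState$fn
  if (is.null(fn))
    stop(structure(class = c("unsupportedFeature", "error", "condition"),
                   list(message = paste("inchiTautomers requested but no",
                                        "tautomer canonicalizer is registered"),
                        call = NULL)))
  fn(.ensureNormalized(mol))
}

# -- stereo validation --------------------------------------------------------

# parity of the permutation taking ord1 onto ord2 (both vectors over the
# same elements); returns NA when they are not rearrangements of each other
.permutationOdd <- function(ord1, ord2) {
  perm <- match(ord1, ord2)
  if (anyNA(perm) || anyDuplicated(perm)) return(NA)
  inv <- 0L
  n <- length(perm)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (perm[i] > perm[j]) inv <- inv + 1L
  inv %% 2L == 1L
}

.stereoConsistent <- function(q, t, mapping, tAdj) {
  qa <- q@atoms; ta <- t@atoms
  qb <- q@bonds; tb <- t@bonds

  # tetrahedral centers
  for (i in which(!is.na(qa$parity))) {
    ti <- mapping[i]
    if (is.na(ta$parity[ti])) next             # undefined never conflicts
    qord <- q@tetraOrder[[i]]
    tord <- t@tetraOrder[[ti]]
    if (is.null(qord) || is.null(tord)) next
    if (length(qord) == 3L) qord <- c(qord, 0L)
    if (length(tord) == 3L) tord <- c(tord, 0L)
    mq <- qord
    mq[qord != 0L] <- mapping[qord[qord != 0L]]
    # a query implicit-H slot stands for the one target neighbor (or the
    # target's own implicit H) not used by any other slot
    if (any(mq == 0L) && !(0L %in% tord)) {
      free <- setdiff(tord, mq)
      if (length(free) != 1L) next
      mq[mq == 0L] <- free
    } else if (0L %in% tord && !all(mq %in% tord)) {
      extra <- setdiff(mq, tord)
      if (length(extra) != 1L) next
      mq[mq == extra] <- 0L
    }
    odd <- .permutationOdd(mq, tord)
    if (is.na(odd)) next
    same <- (qa$parity[i] == ta$parity[ti]) != odd
    if (!same) return(FALSE)
  }

  # double-bond configurations
  for (bi in which(!is.na(qb$config))) {
    m1 <- mapping[qb$a1[bi]]; m2 <- mapping[qb$a2[bi]]
    tbi <- tAdj$bondBetween(m1, m2)
    if (is.na(tbi) || is.na(tb$config[tbi])) next
    mx <- mapping[qb$refA[bi]]; my <- mapping[qb$refB[bi]]
    # orient: target end holding mx, and its reference substituent
    if (tb$a1[tbi] == m1) { refEnd1 <- tb$refA[tbi]; refEnd2 <- tb$refB[tbi]
    } else { refEnd1 <- tb$refB[tbi]; refEnd2 <- tb$refA[tbi] }
    flips <- 0L
    sideOf <- function(mref, end, expected) {
      # 0 = same substituent, 1 = the other substituent, NA = not a neighbor
      if (mref == expected) return(0L)
      others <- setdiff(tAdj$nbr[[end]], c(tb$a1[tbi], tb$a2[tbi]))
      if (mref %in% others) return(1L)
      NA_integer_
    }
    s1 <- sideOf(mx, m1, refEnd1)
    s2 <- sideOf(my, m2, refEnd2)
    if (is.na(s1) || is.na(s2)) next
    flips <- s1 + s2
    eff <- tb$config[tbi]
    if (flips %% 2L == 1L) eff <- if (eff == "cis") "trans" else "cis"
    if (qb$config[bi] != eff) return(FALSE)
  }
  TRUE
}

# -- backtracking search ------------------------------------------------------

.buildAdj <- function(mol) {
  adj <- .adjacency(mol@atoms, mol@bonds)
  key <- new.env(parent = emptyenv())
  b <- mol@bonds
  for (bi in seq_len(nrow(b))) {
    assign(paste(b$a1[bi], b$a2[bi]), bi, envir = key)
    assign(paste(b$a2[bi], b$a1[bi]), bi, envir = key)
  }
  adj$bondBetween <- function(x, y) {
    v <- mget(paste(x, y), envir = key, ifnotfound = NA_integer_)[[1]]
    v
  }
  adj
}

#' Find a substructure or exact-structure mapping
#'
#' Searches for an injective mapping of query atoms onto target atoms under
#' which every mapped atom pair is compatible ([atomCompatible()]) and every
#' query bond lands on a target bond of the same order class.  In exact mode
#' the mapping must additionally be a bijection on atoms and bonds with
#' equal hydrogen counts.  Under `strictStereo`, candidate mappings in which
#' a defined query stereo descriptor contradicts a defined target descriptor
#' are rejected and the search continues; descriptors undefined on either
#' side never conflict.  The backtracking order is fixed (query atoms by
#' candidate count, target candidates by ascending degree then index), so
#' the returned mapping is deterministic.
#'
#' @param query,target [Molecule-class] objects (normalized on the fly).
#' @param opts a [MatchOptions-class].
#' @return an integer vector mapping query atom indices to target atom
#'   indices, or `NULL` when no mapping exists.
#' @examples
#' findMapping(parseSmiles("CO"), parseSmiles("CC(=O)O"))
#' @export
findMapping <- function(query, target, opts = matchOptions()) {
  q <- .applyTautomerMode(query, opts)
  t <- .applyTautomerMode(target, opts)
  nq <- natoms(q); nt <- natoms(t)
  exact <- opts@searchMode == "exact"
  if (nq > nt) return(NULL)
  if (exact && (nq != nt || nrow(q@bonds) != nrow(t@bonds))) return(NULL)

  qa <- q@atoms; ta <- t@atoms
  qAdj <- .buildAdj(q); tAdj <- .buildAdj(t)
  qDeg <- lengths(qAdj$nbr); tDeg <- lengths(tAdj$nbr)

  # compatibility lists
  cand <- vector("list", nq)
  for (i in seq_len(nq)) {
    ok <- integer()
    for (j in seq_len(nt)) {
      if (exact) { if (qDeg[i] != tDeg[j]) next }
      else if (qDeg[i] > tDeg[j]) next
      if (atomCompatible(qa[i, ], ta[j, ], opts)) ok <- c(ok, j)
    }
    if (!length(ok)) return(NULL)
    cand[[i]] <- ok[order(tDeg[ok], ok)]
  }

  # deterministic query ordering: fewest candidates first, preferring atoms
  # adjacent to the already-ordered set (connected search)
  qorder <- integer(0)
  remaining <- seq_len(nq)
  while (length(remaining)) {
    adjacent <- remaining[vapply(remaining, function(i)
      any(qAdj$nbr[[i]] %in% qorder), logical(1))]
    pool <- if (length(adjacent)) adjacent else remaining
    sizes <- lengths(cand[pool])
    pick <- pool[order(sizes, pool)][1L]
    qorder <- c(qorder, pick)
    remaining <- setdiff(remaining, pick)
  }

  mapping <- rep(NA_integer_, nq)
  used <- logical(nt)
  checkStereo <- opts@stereoMode == "strictStereo"

  search <- function(depth) {
    if (depth > nq) {
      if (!checkStereo) return(TRUE)
      return(.stereoConsistent(q, t, mapping, tAdj))
    }
    qi <- qorder[depth]
    mappedNbrs <- qAdj$nbr[[qi]][!is.na(mapping[qAdj$nbr[[qi]]])]
    cands <- cand[[qi]]
    for (tj in cands) {
      if (used[tj]) next
      ok <- TRUE
      for (qn in mappedNbrs) {
        tbi <- tAdj$bondBetween(mapping[qn], tj)
        if (is.na(tbi)) { ok <- FALSE; break }
        qbi <- qAdj$bondBetween(qn, qi)
        if (!bondCompatible(q@bonds$order[qbi], t@bonds$order[tbi])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      mapping[qi] <<- tj
      used[tj] <<- TRUE
      if (search(depth + 1L)) return(TRUE)
      mapping[qi] <<- NA_integer_
      used[tj] <<- FALSE
    }
    FALSE
  }

  if (search(1L)) mapping else NULL
}

#' Does the query match the target?
#'
#' Convenience wrapper around [findMapping()]: `TRUE` when a mapping exists
#' under the given options.  With `tautomerMode = "inchiTautomers"` both
#' structures are first passed through the registered tautomer
#' canonicalizer (see [setTautomerCanonicalizer()]).
#'
#' @inheritParams findMapping
#' @return logical.
#' @examples
#' molMatches(parseSmiles("CO"), parseSmiles("CC(=O)O"))
#' @export
molMatches <- function(query, target, opts = matchOptions()) {
  !is.null(findMapping(query, target, opts))
}
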