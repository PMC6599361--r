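# Implicit valence model, ring perception helpers and the bounded
# aromaticity normalization shared by all readers.

.bondOrderValue <- function(order) {
  vapply(order, function(o) switch(o, single = 1, double = 2, triple = 3,
                                   aromatic = 1.5, tautomeric = 1.5,
                                   stop("unknown bond order: ", o)),
         numeric(1), USE.NAMES = FALSE)
}

# standard valences; S and P take the smallest valence covering the bonds
.standardValence <- function(element, bondSum) {
  ceilSum <- ceiling(bondSum)
  fit <- function(choices) {
    ok <- choices[choices >= ceilSum]
    if (length(ok)) min(ok) else max(choices)
  }
  switch(element,
         H = 0, B = 3, C = 4, N = 3, O = 2,
         P = fit(c(3, 5)), S = fit(c(2, 4, 6)),
         F = 1, Cl = 1, Br = 1, I = 1,
         0)
}

#' Implicit plus explicit hydrogen count of an atom
#'
#' Returns the written bracket H count when present, otherwise fills
#' hydrogens from a fixed standard-valence table (C 4, N 3, O 2, S 2/4/6 and
#' P 3/5 minimal fit, halogens 1) minus the bond-order sum (aromatic bonds
#' count 1.5 and the sum is rounded up), floored at zero.  Formal charges of
#' plus or minus one on N, O or S shift the effective valence by the charge,
#' so e.g. `[O-]` carries one hydrogen fewer and `[N+]` gains a bonding
#' slot.
#'
#' @param mol a [Molecule-class].
#' @param atomIndex atom index (1-based); vectorized.
#' @return non-negative integer hydrogen count(s).
#' @export
totalH <- function(mol, atomIndex = seq_len(natoms(mol))) {
  a <- mol@atoms
  stopifnot(all(atomIndex >= 1L & atomIndex <= nrow(a)))
  bondSum <- numeric(nrow(a))
  b <- mol@bonds
  if (nrow(b)) {
    v <- .bondOrderValue(b$order)
    for (bi in seq_len(nrow(b))) {
      bondSum[b$a1[bi]] <- bondSum[b$a1[bi]] + v[bi]
      bondSum[b$a2[bi]] <- bondSum[b$a2[bi]] + v[bi]
    }
  }
  out <- integer(length(atomIndex))
  for (k in seq_along(atomIndex)) {
    i <- atomIndex[k]
    if (!is.na(a$explicitH[i])) {
      out[k] <- a$explicitH[i]
    } else {
      val <- .standardValence(a$element[i], bondSum[i])
      if (a$element[i] %in% c("N", "O", "S") && abs(a$charge[i]) == 1L)
        val <- val + a$charge[i]
      out[k] <- max(0L, as.integer(val - ceiling(bondSum[i])))
    }
  }
  out
}

# bonds that lie on a cycle: an edge is a ring bond iff its endpoints stay
# connected after removing it
.ringBonds <- function(atomsDf, bondsDf) {
  nb <- nrow(bondsDf)
  if (!nb) return(logical(0))
  n <- nrow(atomsDf)
  inRing <- logical(nb)
  for (bi in seq_len(nb)) {
    # BFS from a1 to a2 avoiding bond bi
    src <- bondsDf$a1[bi]; dst <- bondsDf$a2[bi]
    seen <- logical(n); seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (bj in seq_len(nb)) {
        if (bj == bi) next
        nxt <- if (bondsDf$a1[bj] == cur) bondsDf$a2[bj]
               else if (bondsDf$a2[bj] == cur) bondsDf$a1[bj]
               else next
        if (nxt == dst) { found <- TRUE; break }
        if (!seen[nxt]) { seen[nxt] <- TRUE; queue <- c(queue, nxt) }
      }
    }
    inRing[bi] <- found
  }
  inRing
}

# enumerate simple cycles up to maxLen atoms; returns list of bond-index
# vectors (each with the parallel atom cycle as attribute)
.simpleCycles <- function(atomsDf, bondsDf, maxLen = 12L) {
  nb <- nrow(bondsDf)
  if (!nb) return(list())
  adj <- .adjacency(atomsDf, bondsDf)
  cycles <- list()
  seenKeys <- character()
  # DFS paths starting at each atom; only record cycles whose smallest atom
  # is the start (canonical representative)
  n <- nrow(atomsDf)
  for (start in seq_len(n)) {
    stack <- list(list(path = start, bpath = integer()))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      cur <- fr$path[length(fr$path)]
      nbrs <- adj$nbr[[cur]]
      bnds <- adj$bnd[[cur]]
      for (k in seq_along(nbrs)) {
        nxt <- nbrs[k]
        if (nxt < start) next
        if (nxt == start && length(fr$path) >= 3L) {
          cyc <- fr$path
          bcyc <- c(fr$bpath, bnds[k])
          key0 <- paste(sort(bcyc), collapse = "-")
          if (!(key0 %in% seenKeys)) {
            seenKeys <- c(seenKeys, key0)
            cyc2 <- structure(bcyc, atoms = cyc)
            cycles[[length(cycles) + 1L]] <- cyc2
          }
        } else if (!(nxt %in% fr$path) && length(fr$path) < maxLen) {
          stack[[length(stack) + 1L]] <-
            list(path = c(fr$path, nxt), bpath = c(fr$bpath, bnds[k]))
        }
      }
    }
  }
  cycles
}

#' Normalize aromatic ring representations
#'
#' Brings the two common ways of writing an aromatic ring onto one canonical
#' form so that kekulized and aromatic inputs match consistently: every ring
#' whose atoms were all written aromatic gets aromatic ring bonds, and
#' 6-membered rings of alternating single/double bonds over carbon/nitrogen
#' with no double bond leaving the ring system are converted to aromatic.
#' This is a deliberately bounded rule, not full Hueckel perception.  The
#' function also caches per-atom hydrogen counts (`totalH`) and ring
#' membership (`inRing`) used by the matcher, and is idempotent.
#'
#' An aromatic atom with no aromatic bond at all cannot be part of any
#' aromatic system and raises an error.
#'
#' @param mol a [Molecule-class].
#' @return the normalized [Molecule-class].
#' @examples
#' m1 <- normalizeAromaticity(parseSmiles("C1=CC=CC=C1"))
#' m2 <- normalizeAromaticity(parseSmiles("c1ccccc1"))
#' identical(bonds(m1)$order, bonds(m2)$order)
#' @export
normalizeAromaticity <- function(mol) {
  a <- mol@atoms
  b <- mol@bonds
  cycles <- .simpleCycles(a, b, maxLen = 12L)

  # rule 1: rings written all-aromatic -> aromatic ring bonds
  for (cyc in cycles) {
    at <- attr(cyc, "atoms")
    if (all(a$aromatic[at])) b$order[cyc] <- "aromatic"
  }

  # rule 2: kekulized 6-rings over C/N with alternating single/double
  candidates <- list()
  for (cyc in cycles) {
    at <- attr(cyc, "atoms")
    if (length(at) != 6L) next
    if (!all(a$element[at] %in% c("C", "N"))) next
    ord <- b$order[cyc]
    if (!all(ord %in% c("single", "double"))) next
    alt1 <- identical(ord, rep(c("single", "double"), 3L))
    alt2 <- identical(ord, rep(c("double", "single"), 3L))
    if (alt1 || alt2) candidates[[length(candidates) + 1L]] <- cyc
  }
  if (length(candidates)) {
    candAtoms <- sort(unique(unlist(lapply(candidates, attr, "atoms"))))
    keep <- vapply(candidates, function(cyc) {
      at <- attr(cyc, "atoms")
      # disqualified when a ring atom has a double bond to an atom outside
      # every candidate ring (e.g. a quinone oxygen)
      for (bi in seq_len(nrow(b))) {
        if (b$order[bi] != "double" || bi %in% cyc) next
        ends <- c(b$a1[bi], b$a2[bi])
        inside <- ends %in% at
        if (any(inside) && !all(ends %in% candAtoms)) return(FALSE)
      }
      TRUE
    }, logical(1))
    for (cyc in candidates[keep]) {
      at <- attr(cyc, "atoms")
      a$aromatic[at] <- TRUE
      b$order[cyc] <- "aromatic"
      b$config[cyc] <- NA_character_
      b$refA[cyc] <- NA_integer_
      b$refB[cyc] <- NA_integer_
    }
  }

  # aromatic bonds imply aromatic endpoints
  if (nrow(b)) {
    aro <- b$order == "aromatic"
    a$aromatic[unique(c(b$a1[aro], b$a2[aro]))] <- TRUE
  }

  # unclosable aromaticity: an aromatic atom with no aromatic bond
  aromDeg <- integer(nrow(a))
  if (nrow(b)) {
    for (bi in which(b$order == "aromatic")) {
      aromDeg[b$a1[bi]] <- aromDeg[b$a1[bi]] + 1L
      aromDeg[b$a2[bi]] <- aromDeg[b$a2[bi]] + 1L
    }
  }
  bad <- which(a$aromatic & aromDeg == 0L)
  if (length(bad))
    stop(structure(class = c("aromaticityError", "error", "condition"),
                   list(message = sprintf(
                     "unclosable aromaticity: aromatic atom %d (%s) has no aromatic bond",
                     bad[1L], a$element[bad[1L]]), call = NULL)))

  inRing <- .ringBonds(a, b)
  b$inRing <- if (nrow(b)) inRing else logical(0)
  a$inRing <- FALSE
  if (any(inRing))
    a$inRing[unique(c(b$a1[inRing], b$a2[inRing]))] <- TRUE

  out <- new("Molecule", atoms = a, bonds = b, tetraOrder = mol@tetraOrder,
             source = mol@source)
  out@atoms$totalH <- totalH(out)
  out
}

# normalize only if the cached columns are absent (idempotent entry point
# used by the matcher and fingerprints)
.ensureNormalized <- function(mol) {
  if (all(!is.na(mol@atoms$inRing))) mol else normalizeAromaticity(mol)
}
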