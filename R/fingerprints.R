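# Morgan-style circular fingerprints for similarity scoring and path-feature
# fingerprints for substructure screening.  Identifiers are produced by a
# fixed-constant 64-bit mixing hash compiled into the package, so fingerprints
# are stable across sessions and platforms.

#' Morgan-style connectivity fingerprint
#'
#' Builds the set of circular-environment identifiers used for similarity
#' scoring.  Every atom contributes one identifier per radius `0..maxRadius`:
#' the radius-0 identifier hashes the atom invariant tuple (element, formal
#' charge, isotope or 0, degree, hydrogen count, aromatic flag); each
#' following radius hashes the atom's previous identifier together with the
#' sorted list of (bond order class, neighbor identifier) pairs, the
#' standard iterative Morgan update.  All identifiers are pooled into one
#' set, so the radius-r fingerprint is always a subset of the radius-(r+1)
#' fingerprint and identifiers are invariant under atom reordering.
#'
#' @param mol a [Molecule-class] (normalized on the fly if needed).
#' @param maxRadius maximum environment radius, between 0 and 5 (default 5,
#'   the radius used by the similarity search service).
#' @param detail if `TRUE`, return a data.frame with columns `atom`,
#'   `radius`, `id` instead of a fingerprint object (used to inspect which
#'   environments contribute).
#' @return a [SimFingerprint-class], or a data.frame when `detail = TRUE`.
#' @examples
#' fp <- morganFingerprint(parseSmiles("CCO"))
#' length(fp)
#' @export
morganFingerprint <- function(mol, maxRadius = 5L, detail = FALSE) {
  stopifnot(maxRadius >= 0L, maxRadius <= 5L)
  mol <- .ensureNormalized(mol)
  a <- mol@atoms
  b <- mol@bonds
  n <- nrow(a)
  adj <- .adjacency(a, b)
  degree <- lengths(adj$nbr)

  cur <- character(n)
  tokenLists <- vector("list", n)
  for (i in seq_len(n)) {
    tokenLists[[i]] <- c("atom", a$element[i], as.character(a$charge[i]),
                         as.character(if (is.na(a$isotope[i])) 0L else a$isotope[i]),
                         as.character(degree[i]), as.character(a$totalH[i]),
                         if (a$aromatic[i]) "1" else "0")
  }
  cur <- .cs_hash_token_list(tokenLists)

  recs <- list(data.frame(atom = seq_len(n), radius = 0L, id = cur,
                          stringsAsFactors = FALSE))
  r <- 1L
  while (r <= maxRadius) {
    nxt <- character(n)
    tokenLists <- vector("list", n)
    for (i in seq_len(n)) {
      nbrs <- adj$nbr[[i]]
      toks <- c("env", cur[i])
      if (length(nbrs)) {
        pairTok <- vapply(seq_along(nbrs), function(k) {
          paste0(b$order[adj$bnd[[i]][k]], "|", cur[nbrs[k]])
        }, character(1))
        toks <- c(toks, sort(pairTok))
      }
      tokenLists[[i]] <- toks
    }
    nxt <- .cs_hash_token_list(tokenLists)
    recs[[length(recs) + 1L]] <- data.frame(atom = seq_len(n), radius = r,
                                            id = nxt, stringsAsFactors = FALSE)
    cur <- nxt
    r <- r + 1L
  }
  detailDf <- do.call(rbind, recs)
  if (detail) return(detailDf)
  new("SimFingerprint", ids = sort(unique(detailDf$id)))
}

#' Jaccard (Tanimoto) similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the identifier sets.  Two empty
#' sets score 1 by convention; this case is unreachable for fingerprints of
#' actual molecules, which always contain at least one atom environment.
#'
#' @param a,b [SimFingerprint-class] objects (or bare character vectors of
#'   identifiers).
#' @return similarity score in `[0, 1]`.
#' @examples
#' jaccardSimilarity(morganFingerprint(parseSmiles("CCO")),
#'                   morganFingerprint(parseSmiles("OCC")))
#' @export
jaccardSimilarity <- function(a, b) {
  ia <- if (is(a, "SimFingerprint") || is(a, "ScreenFingerprint")) a@ids else a
  ib <- if (is(b, "SimFingerprint") || is(b, "ScreenFingerprint")) b@ids else b
  ia <- unique(ia); ib <- unique(ib)
  u <- length(union(ia, ib))
  if (u == 0L) return(1)
  length(intersect(ia, ib)) / u
}

#' Path-feature screening fingerprint
#'
#' Enumerates all simple paths of 1 to `maxPathLen` atoms and hashes each
#' path's label sequence, taking the lexicographically smaller of the two
#' traversal directions.  Atoms are labeled only by element and aromatic
#' flag and bonds by order class; charges, isotopes, hydrogen counts and
#' stereo descriptors are deliberately excluded so that the feature set is
#' subgraph-monotone under every wildcard matching mode: if a query is a
#' substructure of a target, every query feature is a target feature, and
#' the subset test can never discard a true match.
#'
#' @param mol a [Molecule-class].
#' @param maxPathLen maximum number of atoms per path (default 7).
#' @return a [ScreenFingerprint-class].
#' @export
screenFingerprint <- function(mol, maxPathLen = 7L) {
  stopifnot(maxPathLen >= 1L)
  mol <- .ensureNormalized(mol)
  a <- mol@atoms
  b <- mol@bonds
  n <- nrow(a)
  adj <- .adjacency(a, b)
  atomLab <- paste0(a$element, ifelse(a$aromatic, "a", "-"))

  keys <- character(0)
  # DFS over simple paths from every start atom
  for (start in seq_len(n)) {
    stack <- list(list(path = start, labs = atomLab[start]))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      forward <- paste(fr$labs, collapse = "!")
      backward <- paste(rev(fr$labs), collapse = "!")
      keys <- c(keys, if (forward <= backward) forward else backward)
      if (length(fr$path) < maxPathLen) {
        cur <- fr$path[length(fr$path)]
        nbrs <- adj$nbr[[cur]]
        for (k in seq_along(nbrs)) {
          nxt <- nbrs[k]
          if (nxt %in% fr$path) next
          stack[[length(stack) + 1L]] <- list(
            path = c(fr$path, nxt),
            labs = c(fr$labs, b$order[adj$bnd[[cur]][k]], atomLab[nxt]))
        }
      }
    }
  }
  keys <- unique(keys)
  ids <- .cs_hash_token_list(lapply(keys, function(k) c("path", k)))
  new("ScreenFingerprint", ids = sort(unique(ids)))
}

# subset test used by the substructure screen
.screenSubset <- function(queryIds, targetIds) {
  all(queryIds %in% targetIds)
}
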