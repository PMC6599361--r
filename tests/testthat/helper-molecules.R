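# Deterministic random (query, target) pair generation for the matcher and
# screening property checks.  Queries are either random connected induced
# subgraphs of the target (guaranteeing informative positives) or unrelated
# small molecules from the fixture pool.

# extract the induced subgraph on a connected random atom subset
randomSubgraph <- function(mol, k) {
  n <- natoms(mol)
  k <- min(k, n)
  a <- atoms(mol)
  b <- bonds(mol)
  start <- sample.int(n, 1L)
  sel <- start
  while (length(sel) < k) {
    border <- unique(c(b$a2[b$a1 %in% sel], b$a1[b$a2 %in% sel]))
    border <- setdiff(border, sel)
    if (!length(border)) break
    sel <- c(sel, border[sample.int(length(border), 1L)])
  }
  sel <- sort(sel)
  remap <- match(seq_len(n), sel)
  keepB <- b$a1 %in% sel & b$a2 %in% sel
  nb <- b[keepB, , drop = FALSE]
  nb$a1 <- remap[nb$a1]; nb$a2 <- remap[nb$a2]
  # drop stereo references pointing outside the subset
  drop <- !is.na(nb$config) & (!(nb$refA %in% which(!is.na(remap))) |
                               !(nb$refB %in% which(!is.na(remap))))
  nb$config[drop] <- NA_character_
  nb$refA <- ifelse(is.na(nb$config), NA_integer_, remap[nb$refA])
  nb$refB <- ifelse(is.na(nb$config), NA_integer_, remap[nb$refB])
  na <- a[sel, , drop = FALSE]
  rownames(na) <- NULL
  na$totalH <- NA_integer_
  na$inRing <- NA
  tetra <- vector("list", length(sel))
  for (j in seq_along(sel)) {
    ord <- mol@tetraOrder[[sel[j]]]
    if (!is.na(na$parity[j]) && !is.null(ord) &&
        all(ord == 0L | ord %in% sel)) {
      tetra[[j]] <- ifelse(ord == 0L, 0L, remap[ord])
    } else {
      na$parity[j] <- NA_character_
    }
  }
  nb$inRing <- rep(NA, nrow(nb))
  new("Molecule", atoms = na, bonds = nb, tetraOrder = tetra,
      source = paste0("subgraph(", sourceText(mol), ")"))
}

# pool of parsed, normalized fixture molecules (targets <= maxAtoms atoms)
fixtureMoleculePool <- function(seed = 42L, n = 60L, maxAtoms = 12L) {
  fx <- generateFixtures(fixtureSpec(seed = seed, nMolecules = n))
  mols <- lapply(fx$smilesTable$structure, function(s)
    normalizeAromaticity(parseSmiles(s)))
  mols[vapply(mols, natoms, 1L) <= maxAtoms]
}

# deterministic list of (query, target) molecule pairs
randomMatchPairs <- function(nPairs, seed = 7L, pool = NULL,
                             maxQueryAtoms = 8L) {
  if (is.null(pool)) pool <- fixtureMoleculePool(seed)
  small <- pool[vapply(pool, natoms, 1L) <= maxQueryAtoms]
  withr::with_seed(seed, {
    pairs <- vector("list", nPairs)
    i <- 1L
    while (i <= nPairs) {
      target <- pool[[sample.int(length(pool), 1L)]]
      query <- if (stats::runif(1) < 0.5) {
        sub <- try(normalizeAromaticity(
          randomSubgraph(target, sample.int(maxQueryAtoms, 1L))),
          silent = TRUE)
        if (inherits(sub, "try-error")) next
        sub
      } else {
        small[[sample.int(length(small), 1L)]]
      }
      pairs[[i]] <- list(query = query, target = target)
      i <- i + 1L
    }
    pairs
  })
}

# minimal V2000 writer used to cross-check the molfile reader against the
# SMILES reader (hydrogen counts are not representable in a plain
# connection table, so callers restrict themselves to molecules without
# explicit H counts)
writeMolfileText <- function(mol) {
  a <- atoms(mol)
  b <- bonds(mol)
  orderCode <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  lines <- c("generated", "  test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)))
  for (i in seq_len(nrow(a)))
    lines <- c(lines, sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$element[i]))
  for (i in seq_len(nrow(b)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              b$a1[i], b$a2[i], orderCode[[b$order[i]]]))
  chg <- which(a$chargeSpecified & a$charge != 0L)
  for (i in chg)
    lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i, a$charge[i]))
  iso <- which(a$isotopeSpecified)
  for (i in iso)
    lines <- c(lines, sprintf("M  ISO  1 %3d %3d", i, a$isotope[i]))
  paste(c(lines, "M  END"), collapse = "\n")
}
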