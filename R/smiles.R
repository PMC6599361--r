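# SMILES reader for the plain-structure subset the search service accepts:
# organic-subset atoms, bracket atoms with isotope/stereo/H-count/charge,
# branches, ring closures (incl. %nn), bond symbols - = # : / \ and aromatic
# lowercase.  No wildcards, no SMARTS, no dot-disconnected fragments.

.organicSubset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromaticSubset <- c("b", "c", "n", "o", "p", "s")

# elements accepted inside brackets (explicit hydrogen atoms are not
# supported as graph nodes; hydrogens live in H counts)
.elementTable <- c(
  "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al", "Si",
  "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co",
  "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y",
  "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb",
  "Te", "I", "Xe", "Cs", "Ba", "La", "W", "Re", "Os", "Ir", "Pt", "Au",
  "Hg", "Tl", "Pb", "Bi")

.smilesError <- function(text, pos, msg) {
  stop(structure(class = c("smilesParseError", "parseError", "error",
                           "condition"),
                 list(message = sprintf("SMILES parse error at position %d in \"%s\": %s",
                                        pos, text, msg),
                      call = NULL)))
}

.newAtomRow <- function(element, aromatic = FALSE, charge = 0L,
                        chargeSpecified = FALSE, isotope = NA_integer_,
                        isotopeSpecified = FALSE, explicitH = NA_integer_,
                        parity = NA_character_) {
  list(element = element, charge = charge, chargeSpecified = chargeSpecified,
       isotope = isotope, isotopeSpecified = isotopeSpecified,
       aromatic = aromatic, explicitH = explicitH, parity = parity)
}

#' Read a molecule from a SMILES string
#'
#' Parses the supported SMILES subset into a [Molecule-class].  Explicitness
#' flags reflect the written text: a bracket charge or isotope sets
#' `chargeSpecified` / `isotopeSpecified`, a bracket `H` count sets
#' `explicitH`, and atoms written in lowercase are flagged aromatic.
#' Bonds between two aromatic atoms default to the aromatic order class.
#' Tetrahedral parities (`@`/`@@`) are stored relative to the neighbor order
#' of first appearance; `/` and `\` bonds around a double bond are resolved
#' to a cis/trans configuration with its reference substituent pair.
#'
#' @param text a single SMILES string.
#' @return a [Molecule-class].
#' @examples
#' mol <- parseSmiles("CCO")
#' natoms(mol)
#' @export
parseSmiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("text must be a non-empty SMILES string")

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atomRows <- list()
  bondRows <- list()   # list(a1, a2, order, sym, fromDir)  (dir bonds keep sym)
  tetra <- list()      # per chiral atom: ordered neighbor vector being built
  dirBonds <- list()   # list(from, to, sym)
  ringOpen <- list()   # key = ring number -> list(atom, sym, pos)

  prev <- NA_integer_
  stack <- integer()
  pendingBond <- NA_character_
  pendingPos <- NA_integer_
  i <- 1L

  addAtom <- function(row) {
    atomRows[[length(atomRows) + 1L]] <<- row
    tetra[length(atomRows)] <<- list(NULL)
    length(atomRows)
  }
  noteNeighbor <- function(atom, nb) {
    # record neighbor order for atoms carrying a tetrahedral mark
    if (atom <= length(atomRows) && !is.na(atomRows[[atom]]$parity))
      tetra[[atom]] <<- c(tetra[[atom]], nb)
  }
  addBond <- function(a1, a2, sym, pos) {
    aroA <- atomRows[[a1]]$aromatic
    aroB <- atomRows[[a2]]$aromatic
    order <- if (is.na(sym)) {
      if (aroA && aroB) "aromatic" else "single"
    } else switch(sym,
      "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
      "/" = "single", "\\" = "single",
      .smilesError(text, pos, paste0("unsupported bond symbol '", sym, "'")))
    if (!is.na(sym) && sym %in% c("/", "\\"))
      dirBonds[[length(dirBonds) + 1L]] <<- list(from = a1, to = a2,
                                                 sym = sym)
    bondRows[[length(bondRows) + 1L]] <<- list(a1 = a1, a2 = a2,
                                               order = order)
  }

  parseBracket <- function(start) {
    # start points at '['; returns list(row, nextPos, hcount)
    j <- start + 1L
    take <- function(re) {
      m <- regmatches(substring(text, j), regexpr(re, substring(text, j)))
      if (length(m) && nzchar(m)) { j <<- j + nchar(m); m } else ""
    }
    iso <- take("^[0-9]+")
    sym <- take("^([A-Z][a-z]?|[a-z])")
    if (!nzchar(sym)) .smilesError(text, j, "expected element symbol in bracket")
    aromatic <- FALSE
    element <- sym
    if (sym %in% .aromaticSubset && !(sym %in% c("Cl", "Br"))) {
      # lowercase single letter => aromatic form
      if (grepl("^[a-z]$", sym)) {
        aromatic <- TRUE
        element <- toupper(sym)
      }
    }
    if (grepl("^[a-z]$", sym) && !aromatic)
      .smilesError(text, j, paste0("unknown element '", sym, "'"))
    if (!aromatic && !(element %in% .elementTable)) {
      if (element == "H")
        .smilesError(text, j, "explicit hydrogen atoms are not supported")
      .smilesError(text, j, paste0("unknown element '", element, "'"))
    }
    chiral <- take("^@@|^@")
    parity <- if (identical(chiral, "@")) "anticlockwise"
              else if (identical(chiral, "@@")) "clockwise"
              else NA_character_
    hPart <- take("^H[0-9]*")
    hcount <- if (nzchar(hPart)) {
      if (nchar(hPart) == 1L) 1L else as.integer(substring(hPart, 2L))
    } else 0L
    hSpecified <- nzchar(hPart)
    chPart <- take("^(\\+[0-9]+|-[0-9]+|\\++|-+)")
    charge <- 0L
    chargeSpecified <- FALSE
    if (nzchar(chPart)) {
      chargeSpecified <- TRUE
      charge <- if (grepl("^[+-][0-9]+$", chPart)) {
        as.integer(chPart)
      } else {
        k <- nchar(chPart)
        if (substring(chPart, 1L, 1L) == "+") k else -k
      }
    }
    if (j > n || chars[j] != "]")
      .smilesError(text, j, "expected ']'")
    # absent H part leaves explicitH unconstrained (NA): hydrogen counts are
    # only pinned down when the input spells them out
    row <- .newAtomRow(element, aromatic = aromatic, charge = charge,
                       chargeSpecified = chargeSpecified,
                       isotope = if (nzchar(iso)) as.integer(iso) else NA_integer_,
                       isotopeSpecified = nzchar(iso),
                       explicitH = if (hSpecified) hcount else NA_integer_,
                       parity = parity)
    list(row = row, nextPos = j + 1L, hcount = if (hSpecified) hcount else 0L,
         hSpecified = hSpecified)
  }

  finishAtom <- function(idx, pos, bracketH = 0L) {
    # connect to previous atom / consume pending bond
    if (!is.na(prev)) {
      addBond(prev, idx, pendingBond, pos)
      noteNeighbor(prev, idx)
      noteNeighbor(idx, prev)
    } else if (!is.na(pendingBond)) {
      .smilesError(text, pos, "bond symbol with no preceding atom")
    }
    # implicit-H slot in the tetrahedral neighbor order comes right after
    # the preceding atom
    if (!is.na(atomRows[[idx]]$parity) && bracketH > 0L)
      tetra[[idx]] <<- c(tetra[[idx]], 0L)
    prev <<- idx
    pendingBond <<- NA_character_
  }

  handleRing <- function(num, pos) {
    key <- as.character(num)
    if (is.null(ringOpen[[key]])) {
      ringOpen[[key]] <<- list(atom = prev, sym = pendingBond, pos = pos)
      # reserve the neighbor-order slot now; fill when the ring closes
      if (!is.na(atomRows[[prev]]$parity))
        tetra[[prev]] <<- c(tetra[[prev]], -num)
    } else {
      open <- ringOpen[[key]]
      ringOpen[[key]] <<- NULL
      if (open$atom == prev)
        .smilesError(text, pos, sprintf("ring bond %d closes on its own atom", num))
      sym <- pendingBond
      if (!is.na(open$sym)) {
        if (!is.na(sym) && sym != open$sym)
          .smilesError(text, pos, sprintf("conflicting bond symbols on ring bond %d", num))
        sym <- open$sym
        # directional ring-open symbol was written open$atom -> closing atom
        addBond(open$atom, prev, sym, pos)
      } else {
        # a directional closing symbol is written prev -> open$atom
        if (!is.na(sym) && sym %in% c("/", "\\")) {
          addBond(prev, open$atom, sym, pos)
        } else {
          addBond(open$atom, prev, sym, pos)
        }
      }
      # fill the reserved stereo slot on the opening atom
      if (!is.na(atomRows[[open$atom]]$parity)) {
        slot <- which(tetra[[open$atom]] == -num)
        if (length(slot)) tetra[[open$atom]][slot[1L]] <<- prev
        else tetra[[open$atom]] <<- c(tetra[[open$atom]], prev)
      }
      noteNeighbor(prev, open$atom)
    }
    pendingBond <<- NA_character_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == " ") { i <- i + 1L; next }
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pendingBond)) .smilesError(text, i, "two consecutive bond symbols")
      pendingBond <- ch
      pendingPos <- i
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) .smilesError(text, i, "branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .smilesError(text, i, "unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev)) .smilesError(text, i, "ring closure with no preceding atom")
      handleRing(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        .smilesError(text, i, "'%' must be followed by two digits")
      if (is.na(prev)) .smilesError(text, i, "ring closure with no preceding atom")
      handleRing(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == "[") {
      br <- parseBracket(i)
      idx <- addAtom(br$row)
      pos <- i
      i <- br$nextPos
      finishAtom(idx, pos, bracketH = br$hcount)
    } else if (ch == ".") {
      .smilesError(text, i, "disconnected (dot) structures are not supported")
    } else {
      # organic subset atom, possibly two letters
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- addAtom(.newAtomRow(two))
        pos <- i
        i <- i + 2L
        finishAtom(idx, pos)
      } else if (ch %in% .organicSubset) {
        idx <- addAtom(.newAtomRow(ch))
        pos <- i
        i <- i + 1L
        finishAtom(idx, pos)
      } else if (ch %in% .aromaticSubset) {
        idx <- addAtom(.newAtomRow(toupper(ch), aromatic = TRUE))
        pos <- i
        i <- i + 1L
        finishAtom(idx, pos)
      } else {
        .smilesError(text, i, paste0("unexpected character '", ch, "'"))
      }
    }
  }

  if (length(stack)) .smilesError(text, n, "unbalanced '('")
  if (length(ringOpen)) .smilesError(text, n,
    paste0("unclosed ring bond(s): ", paste(names(ringOpen), collapse = ", ")))
  if (!is.na(pendingBond)) .smilesError(text, pendingPos, "dangling bond symbol")
  if (!length(atomRows)) .smilesError(text, 1L, "no atoms")

  atomsDf <- do.call(rbind, lapply(atomRows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  atomsDf$totalH <- NA_integer_
  atomsDf$inRing <- NA
  rownames(atomsDf) <- NULL
  bondsDf <- if (length(bondRows)) {
    do.call(rbind, lapply(bondRows, function(r)
      data.frame(a1 = r$a1, a2 = r$a2, order = r$order,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = character(),
               stringsAsFactors = FALSE)
  }
  bondsDf$config <- rep(NA_character_, nrow(bondsDf))
  bondsDf$refA <- rep(NA_integer_, nrow(bondsDf))
  bondsDf$refB <- rep(NA_integer_, nrow(bondsDf))
  bondsDf$inRing <- rep(NA, nrow(bondsDf))

  # resolve /\ pairs around double bonds into cis/trans configurations
  if (length(dirBonds) && nrow(bondsDf)) {
    height <- function(x, a) {
      # relative height of substituent x with respect to double-bond atom a,
      # or NA when no directional bond connects them
      for (d in dirBonds) {
        if (d$from == x && d$to == a) return(if (d$sym == "/") -1L else 1L)
        if (d$from == a && d$to == x) return(if (d$sym == "/") 1L else -1L)
      }
      NA_integer_
    }
    adj <- .adjacency(atomsDf, bondsDf)
    for (bi in which(bondsDf$order == "double")) {
      a <- bondsDf$a1[bi]; b <- bondsDf$a2[bi]
      nbA <- setdiff(adj$nbr[[a]], b)
      nbB <- setdiff(adj$nbr[[b]], a)
      hA <- vapply(nbA, height, integer(1), a = a)
      hB <- vapply(nbB, height, integer(1), a = b)
      ia <- which(!is.na(hA)); ib <- which(!is.na(hB))
      if (length(ia) && length(ib)) {
        x <- nbA[ia[1L]]; y <- nbB[ib[1L]]
        bondsDf$config[bi] <- if (hA[ia[1L]] == hB[ib[1L]]) "cis" else "trans"
        bondsDf$refA[bi] <- x
        bondsDf$refB[bi] <- y
      }
    }
  }

  tetraOrder <- vector("list", nrow(atomsDf))
  for (k in seq_along(tetra))
    if (!is.null(tetra[[k]]) && !is.na(atomsDf$parity[k]))
      tetraOrder[[k]] <- as.integer(tetra[[k]])
  # a parity needs at least 3 ordered neighbors to mean anything
  for (k in seq_len(nrow(atomsDf))) {
    if (!is.na(atomsDf$parity[k]) &&
        (is.null(tetraOrder[[k]]) || length(tetraOrder[[k]]) < 3L)) {
      atomsDf$parity[k] <- NA_character_
      tetraOrder[k] <- list(NULL)
    }
  }

  new("Molecule", atoms = atomsDf, bonds = bondsDf, tetraOrder = tetraOrder,
      source = text)
}

# adjacency lists: nbr[[i]] neighbor atom indices, bnd[[i]] parallel bond rows
.adjacency <- function(atomsDf, bondsDf) {
  n <- nrow(atomsDf)
  nbr <- vector("list", n)
  bnd <- vector("list", n)
  if (nrow(bondsDf)) {
    for (bi in seq_len(nrow(bondsDf))) {
      a <- bondsDf$a1[bi]; b <- bondsDf$a2[bi]
      nbr[[a]] <- c(nbr[[a]], b); bnd[[a]] <- c(bnd[[a]], bi)
      nbr[[b]] <- c(nbr[[b]], a); bnd[[b]] <- c(bnd[[b]], bi)
    }
  }
  list(nbr = nbr, bnd = bnd)
}
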