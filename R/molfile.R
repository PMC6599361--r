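# MDL molfile (V2000) and SDF readers.  Coordinates are read and discarded:
# this is a graph-only service.  Wedge-bond stereochemistry in molfiles is
# ignored (documented limitation); charges and isotopes come from the old
# charge column and the M CHG / M ISO property lines, the latter taking
# precedence as the format prescribes.

.molfileError <- function(msg) {
  stop(structure(class = c("molfileParseError", "parseError", "error",
                           "condition"),
                 list(message = paste0("molfile parse error: ", msg),
                      call = NULL)))
}

#' Read a molecule from an MDL molfile (V2000)
#'
#' Accepts a single-structure V2000 connection table: three header lines, a
#' counts line tagged `V2000`, the atom and bond blocks and optional
#' `M  CHG` / `M  ISO` property lines up to `M  END`.  Charges or isotopes
#' set through property lines (or the legacy atom-block charge column) are
#' marked as specified; all other atoms have unspecified charge.  Bond type
#' 4 is read as aromatic.
#'
#' @param text molfile content as a single string, or a character vector of
#'   lines.
#' @return a [Molecule-class].
#' @export
parseMolfile <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  if (length(lines) < 4L) .molfileError("truncated file (no counts line)")
  counts <- lines[4L]
  if (!grepl("V2000", counts))
    .molfileError("missing or unsupported version tag (expected V2000)")
  readInt <- function(s) {
    v <- suppressWarnings(as.integer(trimws(s)))
    if (is.na(v)) .molfileError(paste0("bad counts field: '", s, "'"))
    v
  }
  nAtoms <- readInt(substr(counts, 1L, 3L))
  nBonds <- readInt(substr(counts, 4L, 6L))
  if (nAtoms < 1L) .molfileError("molecule must have at least one atom")
  if (length(lines) < 4L + nAtoms + nBonds)
    .molfileError("truncated atom or bond block")

  atomLines <- lines[5L:(4L + nAtoms)]
  bondLines <- if (nBonds > 0L) lines[(5L + nAtoms):(4L + nAtoms + nBonds)]
               else character()

  legacyCharge <- function(code) {
    # 0 none, 1 = +3, 2 = +2, 3 = +1, 4 = radical (ignored), 5..7 = -1..-3
    switch(code + 1L, 0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  }

  atomRows <- vector("list", nAtoms)
  for (i in seq_len(nAtoms)) {
    f <- strsplit(trimws(atomLines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 4L) .molfileError(sprintf("bad atom line %d", i))
    sym <- f[4L]
    if (!(sym %in% .elementTable))
      .molfileError(paste0("unknown element '", sym, "' on atom line ", i))
    chgCode <- if (length(f) >= 6L) suppressWarnings(as.integer(f[6L])) else 0L
    if (is.na(chgCode)) chgCode <- 0L
    chg <- if (chgCode >= 0L && chgCode <= 7L) legacyCharge(chgCode) else 0L
    atomRows[[i]] <- .newAtomRow(sym, charge = chg,
                                 chargeSpecified = chg != 0L)
  }

  bondRows <- vector("list", nBonds)
  aromaticAtoms <- integer()
  for (i in seq_len(nBonds)) {
    ln <- bondLines[i]
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) >= 3L && !anyNA(suppressWarnings(as.integer(f[1:3])))) {
      v <- as.integer(f[1:3])
    } else if (nchar(ln) >= 9L) {
      v <- suppressWarnings(as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6),
                                         substr(ln, 7, 9))))
      if (anyNA(v)) .molfileError(sprintf("bad bond line %d", i))
    } else .molfileError(sprintf("bad bond line %d", i))
    a1 <- v[1L]; a2 <- v[2L]; type <- v[3L]
    if (a1 < 1L || a1 > nAtoms || a2 < 1L || a2 > nAtoms || a1 == a2)
      .molfileError(sprintf("bond line %d references invalid atoms", i))
    order <- switch(as.character(type), "1" = "single", "2" = "double",
                    "3" = "triple", "4" = "aromatic",
                    .molfileError(sprintf("unsupported bond type %d", type)))
    if (order == "aromatic") aromaticAtoms <- c(aromaticAtoms, a1, a2)
    bondRows[[i]] <- list(a1 = a1, a2 = a2, order = order)
  }

  # property lines; M CHG and M ISO supersede the legacy charge column
  propStart <- 5L + nAtoms + nBonds
  sawChg <- FALSE
  chgPairs <- list(); isoPairs <- list()
  if (length(lines) >= propStart) {
    for (ln in lines[propStart:length(lines)]) {
      if (grepl("^M  END", ln)) break
      if (grepl("^M  CHG", ln)) {
        f <- as.integer(strsplit(trimws(substring(ln, 7L)), "[[:space:]]+")[[1]])
        sawChg <- TRUE
        cnt <- f[1L]
        for (k in seq_len(cnt))
          chgPairs[[length(chgPairs) + 1L]] <- f[c(2L * k, 2L * k + 1L)]
      } else if (grepl("^M  ISO", ln)) {
        f <- as.integer(strsplit(trimws(substring(ln, 7L)), "[[:space:]]+")[[1]])
        cnt <- f[1L]
        for (k in seq_len(cnt))
          isoPairs[[length(isoPairs) + 1L]] <- f[c(2L * k, 2L * k + 1L)]
      }
    }
  }
  if (sawChg) {
    for (i in seq_len(nAtoms)) {
      atomRows[[i]]$charge <- 0L
      atomRows[[i]]$chargeSpecified <- FALSE
    }
    for (p in chgPairs) {
      if (p[1L] < 1L || p[1L] > nAtoms) .molfileError("M CHG atom out of range")
      atomRows[[p[1L]]]$charge <- p[2L]
      atomRows[[p[1L]]]$chargeSpecified <- TRUE
    }
  }
  for (p in isoPairs) {
    if (p[1L] < 1L || p[1L] > nAtoms) .molfileError("M ISO atom out of range")
    atomRows[[p[1L]]]$isotope <- p[2L]
    atomRows[[p[1L]]]$isotopeSpecified <- TRUE
  }

  atomsDf <- do.call(rbind, lapply(atomRows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  atomsDf$totalH <- NA_integer_
  atomsDf$inRing <- NA
  if (length(aromaticAtoms)) atomsDf$aromatic[unique(aromaticAtoms)] <- TRUE
  bondsDf <- if (nBonds) {
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

  new("Molecule", atoms = atomsDf, bonds = bondsDf,
      tetraOrder = vector("list", nAtoms),
      source = paste(lines, collapse = "\n"))
}

#' Read the records of an SDF file
#'
#' Splits a multi-record SDF (records delimited by `$$$$`) into molfile
#' blocks and associated data fields.
#'
#' @param text SDF content as a single string, a character vector of lines,
#'   or a file path.
#' @return a list of records, each a list with elements `molfile` (string)
#'   and `fields` (named character vector of the record's data items).
#' @export
readSdf <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readChar(text, file.size(text), useBytes = TRUE)
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  recs <- split(lines, cumsum(c(0L, head(grepl("^\\$\\$\\$\\$", lines), -1L))))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    endIdx <- grep("^M  END", rec)
    molEnd <- if (length(endIdx)) endIdx[1L] else length(rec)
    molfile <- paste(rec[seq_len(molEnd)], collapse = "\n")
    fields <- character()
    i <- molEnd + 1L
    while (i <= length(rec)) {
      m <- regmatches(rec[i], regexec("^>.*<([^>]+)>", rec[i]))[[1]]
      if (length(m) == 2L) {
        vals <- character()
        i <- i + 1L
        while (i <= length(rec) && nzchar(trimws(rec[i])) &&
               !grepl("^>", rec[i])) {
          vals <- c(vals, rec[i])
          i <- i + 1L
        }
        fields[m[2L]] <- paste(vals, collapse = "\n")
      } else i <- i + 1L
    }
    out[[length(out) + 1L]] <- list(molfile = molfile, fields = fields)
  }
  out
}
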