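# Molecule model: SMILES and molfile readers, aromaticity normalization,
# implicit hydrogen model.

test_that("SMILES reader produces the expected graphs and explicitness flags", {
  m <- parseSmiles("CCO")
  expect_equal(atoms(m)$element, c("C", "C", "O"))
  expect_equal(nrow(bonds(m)), 2L)
  expect_true(all(bonds(m)$order == "single"))
  expect_false(any(atoms(m)$chargeSpecified))

  tma <- parseSmiles("C[N+](C)(C)C")
  n <- atoms(tma)[2, ]
  expect_equal(n$element, "N")
  expect_equal(n$charge, 1L)
  expect_true(n$chargeSpecified)
  expect_equal(sum(bonds(tma)$a1 == 2 | bonds(tma)$a2 == 2), 4L)

  iso <- parseSmiles("[13C]O")
  expect_equal(atoms(iso)$isotope[1], 13L)
  expect_true(atoms(iso)$isotopeSpecified[1])
  expect_false(atoms(iso)$isotopeSpecified[2])
})

test_that("the adenine query structure parses to the purine graph", {
  ad <- parseSmiles("Nc1ncnc2[nH]cnc12")
  expect_equal(natoms(ad), 10L)
  adn <- normalizeAromaticity(ad)
  # two fused aromatic rings: 10 aromatic ring bonds, 1 single exocyclic
  expect_equal(sum(bonds(adn)$order == "aromatic"), 10L)
  expect_equal(sum(bonds(adn)$order == "single"), 1L)
  expect_equal(sum(atoms(adn)$explicitH == 1L, na.rm = TRUE), 1L)
  expect_equal(sum(atoms(adn)$element == "N"), 5L)
})

test_that("SMILES parsing is deterministic", {
  for (s in c("CCO", "Nc1ncnc2[nH]cnc12", "F/C=C\\F", "CC[C@H](N)C(=O)O")) {
    m1 <- parseSmiles(s)
    m2 <- parseSmiles(s)
    expect_identical(atoms(m1), atoms(m2))
    expect_identical(bonds(m1), bonds(m2))
    expect_identical(m1@tetraOrder, m2@tetraOrder)
  }
})

test_that("malformed SMILES raise positioned parse errors", {
  expect_error(parseSmiles("C1CC"), class = "smilesParseError")    # open ring
  expect_error(parseSmiles("C(C"), class = "smilesParseError")     # open branch
  expect_error(parseSmiles("CC)C"), class = "smilesParseError")
  expect_error(parseSmiles("[Xx]"), class = "smilesParseError")    # unknown element
  expect_error(parseSmiles("C[N"), class = "smilesParseError")     # bad bracket
  expect_error(parseSmiles("CC.CC"), class = "smilesParseError")   # dot
  expect_error(parseSmiles("C=#C"), class = "smilesParseError")
  expect_match(tryCatch(parseSmiles("C1CC"), error = conditionMessage),
               "position")
})

ethanolMolfile <- paste(c(
  "ethanol", "  test", "",
  "  3  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0",
  "  2  3  1  0  0  0  0",
  "M  END"), collapse = "\n")

test_that("molfile reader agrees with the SMILES reader on the same structure", {
  m <- parseMolfile(ethanolMolfile)
  s <- parseSmiles("CCO")
  expect_equal(atoms(m)$element, atoms(s)$element)
  # label-preserving isomorphism in both directions (exact match)
  expect_true(molMatches(s, m, matchOptions(searchMode = "exact")))
  expect_true(molMatches(m, s, matchOptions(searchMode = "exact")))
})

test_that("molfile charge and isotope property lines are honored", {
  withChg <- sub("M  END", "M  CHG  1   2   1\nM  END", ethanolMolfile)
  m <- parseMolfile(withChg)
  expect_equal(atoms(m)$charge[2], 1L)
  expect_true(atoms(m)$chargeSpecified[2])
  expect_false(atoms(m)$chargeSpecified[1])

  withIso <- sub("M  END", "M  ISO  1   1  13\nM  END", ethanolMolfile)
  m2 <- parseMolfile(withIso)
  expect_equal(atoms(m2)$isotope[1], 13L)
  expect_true(atoms(m2)$isotopeSpecified[1])
})

test_that("malformed molfiles are rejected", {
  expect_error(parseMolfile(sub("V2000", "V3000", ethanolMolfile)),
               class = "molfileParseError")
  # empty atom block violates the one-atom minimum
  empty <- paste(c("", "", "", "  0  0  0  0  0  0  0  0  0  0999 V2000",
                   "M  END"), collapse = "\n")
  expect_error(parseMolfile(empty), class = "molfileParseError")
  truncated <- paste(strsplit(ethanolMolfile, "\n")[[1]][1:6], collapse = "\n")
  expect_error(parseMolfile(truncated), class = "molfileParseError")
})

test_that("aromaticity normalization canonizes kekulized benzenoid rings", {
  b1 <- normalizeAromaticity(parseSmiles("c1ccccc1"))
  expect_equal(sum(bonds(b1)$order == "aromatic"), 6L)
  b2 <- normalizeAromaticity(parseSmiles("C1=CC=CC=C1"))
  expect_identical(bonds(b2)$order, bonds(b1)$order)
  expect_identical(atoms(b2)$aromatic, atoms(b1)$aromatic)
  p1 <- normalizeAromaticity(parseSmiles("c1ccncc1"))
  p2 <- normalizeAromaticity(parseSmiles("C1=CC=NC=C1"))
  expect_identical(bonds(p2)$order, bonds(p1)$order)
  # acyclic molecules pass through unchanged
  e <- parseSmiles("CCO")
  en <- normalizeAromaticity(e)
  expect_identical(bonds(en)$order, bonds(e)$order)
  # a quinone-like exocyclic double bond blocks the conversion
  q <- normalizeAromaticity(parseSmiles("O=C1C=CC(=O)C=C1"))
  expect_false(any(bonds(q)$order == "aromatic"))
})

test_that("aromaticity normalization is idempotent on fixture molecules", {
  fx <- generateFixtures(fixtureSpec(seed = 11L, nMolecules = 25L))
  for (s in fx$smilesTable$structure) {
    m1 <- normalizeAromaticity(parseSmiles(s))
    m2 <- normalizeAromaticity(m1)
    expect_identical(bonds(m1)$order, bonds(m2)$order)
    expect_identical(atoms(m1)$aromatic, atoms(m2)$aromatic)
  }
})

test_that("an aromatic atom with no aromatic bond is unclosable", {
  expect_error(normalizeAromaticity(parseSmiles("cCC")),
               class = "aromaticityError")
  # but open aromatic fragments (queries) are fine
  expect_silent(normalizeAromaticity(parseSmiles("cc")))
})

test_that("the implicit hydrogen model fills standard valences", {
  expect_equal(totalH(parseSmiles("C")), 4L)
  expect_equal(totalH(normalizeAromaticity(parseSmiles("CCO")), 3L), 1L)
  ad <- normalizeAromaticity(parseSmiles("Nc1ncnc2[nH]cnc12"))
  nh <- which(atoms(ad)$explicitH == 1L)
  expect_equal(totalH(ad, nh), 1L)
  # charge adjustment on +-1 N/O/S
  expect_equal(totalH(normalizeAromaticity(parseSmiles("CC[O-]")), 3L), 0L)
  expect_equal(totalH(parseSmiles("[NH4+]"), 1L), 4L)
  expect_equal(totalH(normalizeAromaticity(parseSmiles("C[N+](C)(C)C")), 2L), 0L)
  # benzene CH
  b <- normalizeAromaticity(parseSmiles("c1ccccc1"))
  expect_true(all(totalH(b) == 1L))
})

test_that("generated molfiles and SMILES yield isomorphic molecules", {
  pool <- fixtureMoleculePool(seed = 5L, n = 30L)
  plain <- Filter(function(m) all(is.na(atoms(m)$explicitH)), pool)
  exact <- matchOptions(searchMode = "exact")
  for (m in plain[seq_len(min(10L, length(plain)))]) {
    mf <- parseMolfile(writeMolfileText(m))
    expect_equal(natoms(mf), natoms(m))
    expect_true(molMatches(m, mf, exact))
    expect_true(molMatches(mf, m, exact))
  }
})
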