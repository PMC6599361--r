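# Substructure / exact matching under the full mode semantics.

test_that("atom compatibility implements the charge and isotope mode rules", {
  normAtoms <- function(s) atoms(normalizeAromaticity(parseSmiles(s)))
  qN <- normAtoms("CN")[2, ]                    # charge unspecified
  tN <- normAtoms("C[N+](C)(C)C")[2, ]          # +1, specified
  expect_true(atomCompatible(qN, tN, matchOptions()))
  expect_false(atomCompatible(qN, tN,
                              matchOptions(chargeMode = "defaultChargeAsZero")))
  expect_true(atomCompatible(qN, tN,
                             matchOptions(chargeMode = "ignoreCharges")))

  qC <- normAtoms("CC")[1, ]                    # isotope unspecified
  tC <- normAtoms("[13CH3]C")[1, ]
  expect_false(atomCompatible(qC, tC, matchOptions()))
  expect_true(atomCompatible(qC, tC,
                             matchOptions(isotopeMode = "defaultIsotopeAsAny")))
  expect_true(atomCompatible(qC, tC,
                             matchOptions(isotopeMode = "ignoreIsotopes")))

  qO <- normAtoms("CO")[2, ]
  expect_false(atomCompatible(qC, qO, matchOptions()))  # element mismatch
})

test_that("bond compatibility is order-class equality", {
  expect_true(bondCompatible("single", "single"))
  expect_true(bondCompatible("double", "double"))
  expect_false(bondCompatible("single", "aromatic"))
  expect_false(bondCompatible("double", "single"))
})

test_that("substructure and exact modes differ as defined", {
  q <- parseSmiles("CCO"); t <- parseSmiles("CCCO")
  expect_false(is.null(findMapping(q, t)))
  expect_null(findMapping(q, t, matchOptions(searchMode = "exact")))
  # identity under exact mode, and atom-order independence
  for (s in c("CCO", "c1ccccc1", "CC(=O)O", "Nc1ncnc2[nH]cnc12"))
    expect_true(molMatches(parseSmiles(s), parseSmiles(s),
                           matchOptions(searchMode = "exact")))
  expect_true(molMatches(parseSmiles("OCC"), parseSmiles("CCO"),
                         matchOptions(searchMode = "exact")))
  expect_true(molMatches(parseSmiles("CO"), parseSmiles("CC(=O)O")))
  expect_false(molMatches(parseSmiles("cc"), parseSmiles("CCO")))
})

test_that("the pinned ring [nH] makes adenine tautomer-sensitive", {
  we <- workedExamples()
  adenine <- parseSmiles(we$molecules[["adenine"]])
  adenosine <- parseSmiles(we$molecules[["adenosine"]])
  # with tautomers ignored, the written H placement must match exactly and
  # the substituted ring nitrogen of adenosine cannot carry it
  expect_false(molMatches(adenine, adenosine, matchOptions()))
  # tautomer-aware matching lifts the mobile-H placement
  expect_true(molMatches(adenine, adenosine,
                         matchOptions(tautomerMode = "inchiTautomers")))
  # and an unsubstituted purine keeps matching either way
  expect_true(molMatches(adenine, adenine, matchOptions()))
})

test_that("double-bond stereochemistry conflicts remove matches under strictStereo", {
  trans <- parseSmiles("F/C=C/F")
  cis <- parseSmiles("F/C=C\\F")
  strict <- matchOptions(stereoMode = "strictStereo")
  expect_null(findMapping(trans, cis, strict))
  expect_null(findMapping(cis, trans, strict))
  expect_false(is.null(findMapping(trans, cis)))          # ignoreStereo
  expect_false(is.null(findMapping(trans, trans, strict)))
  expect_false(is.null(findMapping(cis, cis, strict)))
  # undefined target stereo never conflicts
  plain <- parseSmiles("FC=CF")
  expect_false(is.null(findMapping(trans, plain, strict)))
})

test_that("tetrahedral parity conflicts remove matches under strictStereo", {
  l <- parseSmiles("N[C@@H](C)C(=O)O")
  d <- parseSmiles("N[C@H](C)C(=O)O")
  strict <- matchOptions(searchMode = "exact", stereoMode = "strictStereo")
  loose <- matchOptions(searchMode = "exact")
  expect_false(molMatches(l, d, strict))
  expect_true(molMatches(l, d, loose))
  expect_true(molMatches(l, l, strict))
  # the same configuration written from the other end still matches
  l2 <- parseSmiles("OC(=O)[C@H](C)N")
  expect_true(molMatches(l, l2, strict))
  expect_false(molMatches(d, l2, strict))
})

test_that("an unregistered tautomer canonicalizer raises an unsupported-feature error", {
  old <- setTautomerCanonicalizer(NULL)
  on.exit(setTautomerCanonicalizer(old))
  expect_error(molMatches(parseSmiles("CCO"), parseSmiles("CCO"),
                          matchOptions(tautomerMode = "inchiTautomers")),
               class = "unsupportedFeature")
})

test_that("the matcher agrees with exhaustive enumeration across the mode grid", {
  pool <- fixtureMoleculePool(seed = 42L)
  pairs <- randomMatchPairs(60L, seed = 17L, pool = pool)
  grid <- modeGrid()
  for (p in pairs) {
    for (gi in seq_len(nrow(grid))) {
      opts <- matchOptions(searchMode = grid$searchMode[gi],
                           chargeMode = grid$chargeMode[gi],
                           isotopeMode = grid$isotopeMode[gi],
                           stereoMode = grid$stereoMode[gi])
      expect_equal(molMatches(p$query, p$target, opts),
                   oracleMatches(p$query, p$target, opts),
                   info = paste(sourceText(p$query), "|",
                                sourceText(p$target), "|",
                                paste(unlist(grid[gi, ]), collapse = " ")))
    }
  }
})

test_that("exact matching is an equivalence relation on fixture molecules", {
  pool <- fixtureMoleculePool(seed = 13L, n = 40L)
  pool <- pool[seq_len(min(18L, length(pool)))]
  exact <- matchOptions(searchMode = "exact")
  n <- length(pool)
  rel <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      rel[i, j] <- molMatches(pool[[i]], pool[[j]], exact)
  expect_true(all(diag(rel)))                 # reflexive
  expect_identical(rel, t(rel))               # symmetric
  for (i in seq_len(n))                       # transitive
    for (j in seq_len(n))
      if (rel[i, j])
        expect_identical(rel[i, ], rel[j, ])
})

test_that("substructure matching is transitive on fixture triples", {
  pool <- fixtureMoleculePool(seed = 31L, n = 40L)
  withr::with_seed(32L, {
    for (k in 1:40) {
      idx <- sample.int(length(pool), 3L, replace = TRUE)
      q <- pool[[idx[1]]]; t <- pool[[idx[2]]]; u <- pool[[idx[3]]]
      premise <- molMatches(q, t) && molMatches(t, u)
      expect_true(!premise || molMatches(q, u))
    }
  })
})

test_that("wildcard relaxation grows the match set monotonically", {
  pool <- fixtureMoleculePool(seed = 51L)
  queries <- list(parseSmiles("CC(=O)O"), parseSmiles("CO"),
                  parseSmiles("[13CH3]O"), parseSmiles("F/C=C/F"),
                  parseSmiles("CN"))
  matchSet <- function(q, opts)
    which(vapply(pool, function(t) molMatches(q, t, opts), logical(1)))
  for (q in queries) {
    chAny <- matchSet(q, matchOptions())
    chZero <- matchSet(q, matchOptions(chargeMode = "defaultChargeAsZero"))
    chIgn <- matchSet(q, matchOptions(chargeMode = "ignoreCharges"))
    expect_true(all(chZero %in% chAny))
    expect_true(all(chAny %in% chIgn))
    isStd <- matchSet(q, matchOptions())
    isAny <- matchSet(q, matchOptions(isotopeMode = "defaultIsotopeAsAny"))
    isIgn <- matchSet(q, matchOptions(isotopeMode = "ignoreIsotopes"))
    expect_true(all(isStd %in% isAny))
    expect_true(all(isAny %in% isIgn))
    stStrict <- matchSet(q, matchOptions(stereoMode = "strictStereo"))
    stIgn <- matchSet(q, matchOptions())
    expect_true(all(stStrict %in% stIgn))
  }
})

test_that("default-mode matching agrees with an external toolkit on plain molecules", {
  # neutral, isotope-free, stereo-free structures: every mode choice
  # coincides, so the default modes are comparable with a generic
  # substructure matcher
  smiles <- c("CCO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1", "CCN", "CCCC",
              "c1ccncc1", "CC(C)O", "C=CC", "OCC(O)CO")
  queries <- c("CO", "CC", "cc", "C=C", "c1ccccc1", "CCO", "N", "O")
  cases <- expand.grid(q = queries, t = smiles, stringsAsFactors = FALSE)
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "cases = json.load(open(sys.argv[1]))",
    "out = []",
    "for q, t in cases:",
    "    qm = Chem.MolFromSmarts(q)",
    "    tm = Chem.MolFromSmiles(t)",
    "    out.append(bool(tm.HasSubstructMatch(qm)))",
    "print(json.dumps(out))", sep = "\n")
  caseFile <- tempfile(fileext = ".json")
  scriptFile <- tempfile(fileext = ".py")
  jsonlite::write_json(unname(Map(c, cases$q, cases$t)), caseFile)
  writeLines(script, scriptFile)
  res <- system2("python", c(scriptFile, caseFile), stdout = TRUE)
  expected <- unlist(jsonlite::fromJSON(res))
  got <- mapply(function(q, t)
    molMatches(parseSmiles(q), parseSmiles(t)), cases$q, cases$t)
  expect_equal(unname(got), expected)
})
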