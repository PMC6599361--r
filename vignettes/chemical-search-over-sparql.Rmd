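---
title: "Chemical structure search over SPARQL: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical structure search over SPARQL: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemSparql)
```

## The problem

Small-molecule databases publish their metadata as RDF and answer SPARQL
queries, which makes heterogeneous queries across databases possible.  What
the RDF model cannot do naturally is *chemical structure search*: the
relation "molecule T contains query Q as a substructure" holds for an
unbounded set of structures, so it cannot be materialized as stored
triples.  ChemSparql implements the standard resolution at desk scale: a
SPARQL endpoint whose query engine recognizes certain triple patterns as
*procedure calls*.  A pattern such as

```
?COMPOUND sachem:substructureSearch [
    sachem:query "Nc1ncnc2[nH]cnc12" ;
    sachem:tautomerMode sachem:inchiTautomers ] .
```

is ordinary SPARQL syntax — any standards-compliant client, or a federated
query from another endpoint, can submit it — but the engine executes it as
a substructure search and binds `?COMPOUND` to the matching compound IRIs.
Because the extension changes no syntax, it is transparent: a query using
no chemical-search predicate evaluates exactly as it would on a plain
SPARQL store.

## The matching model

A molecule is a labeled graph.  Atoms carry element, formal charge,
isotope mass number, aromaticity, an optional explicit hydrogen count and
an optional tetrahedral parity; each of the optional annotations also
records whether it was *written* in the input, because the search modes
give unwritten annotations configurable semantics.  Bonds carry an order
class (single, double, triple, aromatic) and, for double bonds, an
optional cis/trans configuration with its pair of reference substituents.

Substructure search asks for an injective mapping of query atoms onto
target atoms such that every mapped atom pair is compatible and every
query bond lands on a target bond of the same order class (a subgraph
monomorphism).  Exact search additionally requires a bijection on atoms
and bonds with equal hydrogen counts.  Atom compatibility requires equal
element symbols and aromatic flags, plus the mode rules:

* **Charge modes.** `defaultChargeAsAny`: an unwritten query charge is a
  wildcard; a written one must match.  `defaultChargeAsZero`: an unwritten
  query charge means "uncharged".  `ignoreCharges`: charges are not
  compared at all.
* **Isotope modes.** `defaultIsotopeAsStandard`: an unlabeled query atom
  matches only unlabeled target atoms.  `defaultIsotopeAsAny`: unlabeled
  is a wildcard.  `ignoreIsotopes`: no comparison.
* **Stereo modes.** `strictStereo` rejects any otherwise-valid mapping in
  which a defined query descriptor (tetrahedral parity or double-bond
  cis/trans) maps onto a defined target descriptor that contradicts it;
  a descriptor undefined on either side never conflicts.  We read
  "remove results with conflicting stereochemistry" literally: only
  contradictions are removed, "query defined / target undefined" is not a
  conflict.  `ignoreStereo` skips the check.
* **Tautomer modes.** Under `ignoreTautomers`, a written `[nH]` hydrogen
  count on an aromatic ring nitrogen is enforced exactly; this pins the
  mobile hydrogen where the query wrote it, which is why adenine written
  as `Nc1ncnc2[nH]cnc12` does *not* match adenosine (whose corresponding
  ring nitrogen carries the ribose instead of an H).  Under
  `inchiTautomers` both structures pass through a pluggable tautomer
  canonicalizer before matching; the default plug-in drops hydrogen
  placements on ring N/O atoms and unifies ring bond orders in
  N/O-containing ring systems into one "tautomeric" class.  That bounded
  mobile-hydrogen relaxation is sufficient for heteroaromatic cases such
  as "any tautomeric form of adenine"; it is *not* the InChI mobile-H
  algorithm, and exocyclic keto/enol tautomerism is outside its reach
  (a documented limitation; the interface accepts a better canonicalizer
  via `setTautomerCanonicalizer()`).

The search itself is a VF2-style backtracking over candidate atom
assignments.  Query atoms are ordered connected-first by ascending
candidate count, target candidates by ascending degree with index
tie-break; together with the post-mapping stereo filter this makes every
result deterministic.  Stereo validation happens after a complete mapping
is found (and the search continues past rejected mappings) — correctness
over micro-optimization at this scale.

The default mode vector, used whenever a procedure-call argument is
omitted, is: substructure search, `defaultChargeAsAny`,
`defaultIsotopeAsStandard`, `ignoreStereo`, `ignoreTautomers`.  The mode
vocabulary defines the enumerations but not the server defaults, so these
defaults are this package's own declaration, chosen so that the plainest
query (a bare SMILES) behaves like a chemist's sketch: charges drawn are
required, charges not drawn are unconstrained, and isotopes follow the
convention that an unlabeled atom is the standard isotope.

## Hydrogen and aromaticity models

Hydrogen counts are implicit.  `totalH()` returns the written bracket
count when present, otherwise fills from a fixed standard-valence table
(C 4, N 3, O 2, S 2/4/6 and P 3/5 minimal fit, halogens 1), subtracting
the bond order sum (aromatic bonds count 1.5, the sum is rounded up) and
flooring at zero.  Formal charges of ±1 on N, O and S shift the effective
valence by the charge — `[O-]` loses a hydrogen, `[N+]` gains a bonding
slot.  This is deliberately the smallest model that makes the worked
examples well defined; exotic valence states are out of scope.

Aromaticity is normalized, not perceived.  Lowercase SMILES input is
trusted; in addition, 6-membered rings of alternating single/double bonds
over C/N with no double bond escaping the ring system are converted to the
aromatic class, so `C1=CC=CC=C1` and `c1ccccc1` are the same molecule
after normalization.  There is no general Hückel perception: a kekulized
5-membered heteroaromatic ring, or an exotic fused system, will not be
aromatized, and such inputs match only inputs written the same way.  An
aromatic atom with no aromatic bond at all is an error ("unclosable"
aromaticity), while open aromatic fragments such as the query `cc` are
legal — their rings complete in the target.

## Fingerprints

Similarity scoring uses Morgan-style connectivity fingerprints with a
radius of up to 5.  Every atom contributes one identifier per radius
0..5: radius 0 hashes the invariant tuple (element, charge, isotope-or-0,
degree, total hydrogen count, aromatic flag); radius r hashes the
radius-(r−1) identifier together with the sorted list of (bond class,
neighbor identifier) pairs.  Identifiers are pooled into a plain set — no
bit folding — so Jaccard similarity |A∩B|/|A∪B| is exact and the
radius-r set is always contained in the radius-(r+1) set.  Hashing uses
fixed FNV-1a/splitmix64 constants compiled into the package, which makes
identifiers stable across platforms and sessions.  J(∅,∅)=1 by
convention; it is unreachable for real molecules, which always have at
least one atom environment.  The atom invariant tuple and the hash are
this package's declared choices; the similarity definition fixes only
"Morgan-style, radius up to 5, Jaccard".

Substructure screening uses a second, coarser fingerprint: identifiers of
all simple paths of 1–7 atoms labeled only by (element, aromatic flag) and
bond class, hashed in the lexicographically smaller direction.  Charges,
isotopes, hydrogen counts and stereo are *excluded from the labels on
purpose*: every matching mode can only relax those annotations, so if a
query matches a target under any charge/isotope/stereo mode, every query
path is present in the target and the subset test
`screen(Q) ⊆ screen(T)` cannot discard a true match.  Screening is a
speed device only; searches verify every surviving candidate with the
full matcher, and the test suite asserts set-equality between screened
and unscreened searches.  Under `inchiTautomers` the screen is bypassed
entirely (every record is verified), because the canonicalized tautomeric
bond class is outside the screening label alphabet; at the indexed sizes
this package targets, correctness is worth the linear pass.  The maximum
path length 7 balances pruning power against index size and is
configurable.

## The SPARQL engine

The engine evaluates a deliberately small SELECT subset — PREFIX,
triple patterns with the `;`/`,`/`[]` abbreviations, FILTER with
comparisons and boolean connectives, DISTINCT, ORDER BY, LIMIT, OFFSET —
directly over an in-memory triple store.  Everything else (OPTIONAL,
UNION, SERVICE, property paths, aggregates, built-in calls) raises an
explicit unsupported-feature error naming the construct, never silent
misbehavior.  Procedure arguments must be constants; the vocabulary's
usage examples never bind them from elsewhere in the query, and a
variable argument raises the unsupported-feature error rather than
guessing a semantics.

Evaluation order is fixed: invocations run first (their arguments are
constants), then residual patterns join in plan order via deterministic
nested-loop natural joins, then filters (a type error inside a filter
removes the row, mirroring SPARQL's error-as-unbound treatment), then
ORDER BY / DISTINCT / OFFSET / LIMIT.  Substructure results are
unstructured: the pattern's subject is bound directly to compound IRIs,
in dataset load order (the result of a substructure search carries no
score, so load order is the natural deterministic choice).  Similarity
results are structured: each hit binds the subject to a fresh blank node
carrying `sachem:compound` and `sachem:score` (an `xsd:double`) as
*virtual triples* that exist only while the query that created them is
evaluated; they are never materialized into the store.  The similarity
cutoff defaults to 0.8 and is inclusive — "minimum score" is read as an
attained minimum; ties in score are broken by IRI for determinism, and
`topn` truncates after sorting.  `topn` has no default: absent means
unlimited.

The `sachem:` vocabulary base IRI is configurable
(`sachemVocabulary(base = ...)`); queries must use whatever IRI the
server is configured with.

## Endpoint and formats

The HTTP endpoint implements the query operation of the SPARQL 1.1
protocol on `httpuv`: GET with `?query=`, POST with a URL-encoded form or
an `application/sparql-query` body, one route per dataset
(`/sparql/endpoint/<name>`, mirroring the per-dataset endpoint layout),
content negotiation over the four standard result media types with JSON
as the default when the client does not express a preference.  Query
errors are 400 with a plain-text message naming the problem; unknown
datasets are 404.  The serializers follow the W3C formats: JSON and XML
carry full term structure; TSV keeps Turtle-like term syntax; CSV carries
plain lexical forms and therefore loses term kinds — a divergence between
the two tabular formats that the standards themselves prescribe.  Blank
nodes receive stable per-response labels in order of first occurrence, so
repeated serializations of one result set are byte-identical.

## The synthetic dataset generator

All tests run against generated data; nothing is downloaded.  The
generator (`generateFixtures()`) composes molecules from vetted SMILES
grammar templates in eight families — alkanes, alcohols, amines,
aromatics, charged species, isotopically labeled species, stereo pairs
and fused-ring systems — so chemical validity holds by construction
rather than by post-hoc filtering.  Each requested family contributes a
guaranteed substructure-related pair, and the output always contains a
charge-annotation pair, an isotope pair, a cis/trans pair and one
structure written in two atom orders.  Everything derives from the seed:
the same spec writes byte-identical files.  What the generator does *not*
emulate: realistic drug-like property distributions, molecule sizes
beyond ~15 heavy atoms, tautomer-rich scaffolds beyond the purine
example, or malformed real-world SDF quirks.  Passing tests therefore
demonstrate the search semantics and the service contract, not
chemistry-space coverage of any production database.

Correctness of the matcher is established against an independent
brute-force oracle (exhaustive enumeration of injective mappings in plain
index order, written separately from the production matcher) across the
full 3×3×2×2 grid of charge × isotope × stereo × search modes, on
hundreds of randomized (query ≤ 8 atoms, target ≤ 12 atoms) pairs drawn
from the generator — induced connected subgraphs of targets (guaranteed
informative positives) mixed with unrelated small molecules.  Problem
sizes in the shipped test-and-acceptance runs — 500 pairs × 36 modes for
oracle equivalence, 1000 pairs for screening soundness, 45-molecule
indexes for the search-level properties — were chosen to exercise every
mode branch several hundred times while keeping a full run in the
minutes range on a single core.  A small cross-check against RDKit's
substructure matcher runs on plain neutral molecules, where every mode
choice coincides.

## Numerical and degenerate-input choices

* Parsing is deterministic; parse errors name the offending position.
* Dot-disconnected SMILES, SMARTS syntax, wildcard atoms and explicit
  hydrogen atoms (`[H]` as a graph node) are rejected, not approximated.
  Isotopes, charges, `@`/`@@` and `/`\\ `\\` are supported in brackets.
* Molfile input is V2000 only; coordinates are discarded (graph-only
  service) and wedge-bond stereo is ignored — stereo-aware matching of
  molfile-sourced structures is a known limitation.  `M CHG`/`M ISO`
  supersede the legacy charge column, as the format prescribes.
* A tetrahedral parity needs at least three recorded neighbors to be
  meaningful; parities on atoms with fewer are dropped at parse time.
* `topn = 0` is a legal request for zero results; an empty hit list is a
  normal result, not an error.
* Indexing skips unparseable records with a warning and a count;
  duplicate IRIs are an error because index lookups must be exact.
* Scores are serialized with up to 15 significant digits, enough to
  round-trip the rational values Jaccard produces at these set sizes.

## Known limitations

Beyond those noted above: no canonical SMILES writer, no depiction, no
InChI; no federation *client* (the endpoint is a federation target — any
SPARQL 1.1 client can reach it — but it does not execute SERVICE clauses
itself); no incremental index updates; single-process in-memory store,
sized for thousands of compounds, not the hundred-million-compound scale
of production deployments.
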