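# ChemSparql

Interoperable chemical structure search over SPARQL, at desk scale.

Chemical databases increasingly publish their metadata as RDF and answer
SPARQL queries, but substructure and similarity relations between
molecules cannot be stored as triples — the relation holds for an
unbounded set of structures.  ChemSparql is an R implementation of the
standard way out: a SPARQL endpoint whose query engine recognizes
**procedure-call patterns** — syntactically ordinary triple patterns
whose predicate belongs to a chemical-search vocabulary — and answers
them by running substructure or similarity searches over an indexed
small-molecule dataset, returning standard SPARQL result formats.  Any
generic SPARQL client, including a federated query from another endpoint,
can use the service without knowing it is anything but a triple store.

It is intended for cheminformaticians and semantic-web developers who
want a self-contained, inspectable implementation of the pattern: a
molecular graph model with SMILES and MDL molfile readers, a
mode-configurable subgraph-isomorphism matcher, Morgan/Jaccard similarity
scoring, a no-false-negative path-feature screen, an in-memory RDF store
with a SPARQL SELECT evaluator, the four W3C result serializations, an
HTTP endpoint speaking the SPARQL 1.1 protocol, and a deterministic
synthetic dataset generator so that everything is testable offline.

## The model in brief

*Substructure search* finds all compounds T admitting an injective map of
the query graph Q onto T preserving atom and bond labels; *exact search*
requires a bijection including hydrogen counts.  Atom compatibility is
mode-configurable: unspecified charges may be wildcards
(`defaultChargeAsAny`), zero (`defaultChargeAsZero`) or ignored; likewise
isotopes; `strictStereo` removes mappings whose defined tetrahedral or
cis/trans descriptors contradict; tautomer-aware matching canonicalizes
mobile hydrogens on N/O ring systems before matching.

*Similarity search* scores each compound by Jaccard similarity

    J(A, B) = |A ∩ B| / |A ∪ B|

over Morgan-style circular fingerprints of radius up to 5 (unfolded
identifier sets, fixed cross-platform hash) and returns hits with
score ≥ cutoff (default 0.8) as structured results carrying
`sachem:compound` and `sachem:score`.

## Worked example

Index the curated example molecules and run the tautomer-aware
substructure query for adenine:

```r
library(ChemSparql)
we  <- workedExamples()
idx <- buildIndex(data.frame(
  iri = paste0("http://example.org/compound/", names(we$molecules)),
  structure = unname(we$molecules), format = "smiles"), name = "worked")
idx
#> CompoundIndex 'worked': 9 compounds

cat(we$queries[["substructure"]])
#> PREFIX sachem: <http://bioinfo.uochb.cas.cz/rdf/v1.0/sachem#>
#> SELECT ?COMPOUND WHERE {
#>   ?COMPOUND sachem:substructureSearch [
#>       sachem:query "Nc1ncnc2[nH]cnc12" ;
#>       sachem:tautomerMode sachem:inchiTautomers ].
#> }

rs <- evaluateQuery(parseSparql(we$queries[["substructure"]]), index = idx)
cat(rawToChar(serializeResults(rs, "csv")))
#> COMPOUND
#> http://example.org/compound/adenine
#> http://example.org/compound/adenosine
```

Both adenine itself and adenosine are returned: under tautomer-aware
matching the mobile ring hydrogen of the query is not pinned, so the
purine core matches even where the ring nitrogen carries the ribose.
With the default `ignoreTautomers` the same search returns only adenine,
because the written `[nH]` placement is then enforced exactly:

```r
substructureSearch(idx, we$molecules[["adenine"]])
#> [1] "http://example.org/compound/adenine"

similaritySearch(idx, we$molecules[["adenine"]], cutoff = 0.5)
#>                              compound score
#> 1 http://example.org/compound/adenine     1
```

The same queries work over HTTP against a generic SPARQL client:

```r
srv <- startEndpoint(list(worked = list(index = idx)), port = 8080)
# GET http://127.0.0.1:8080/sparql/endpoint/worked?query=...
# Accept: application/sparql-results+json | +xml | text/csv | text/tsv
stopEndpoint(srv)
```

A command-line interface covers the same surface:

```sh
chemsparql fixtures --out fx/ --seed 7
chemsparql index --smiles fx/fixtures.tsv --turtle fx/fixtures.ttl --out ds/
chemsparql query ds/ query.rq --format csv
chemsparql serve --data demo=ds/ --port 8080
```

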