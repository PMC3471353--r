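# sparqlcompose

Context-sensitive, multilingual completion for SPARQL query composition.

## The problem

Life-science ontologies increasingly follow the best practice of *opaque
identifiers*: a predicate is named `SIO_000062`, not `isParticipantIn`, so
that its meaning lives in language-tagged `rdfs:label` / `rdfs:comment`
annotations rather than in the URI itself. That is good ontology design —
identifiers stay stable as labels evolve, and one URI can carry labels in
any number of languages — but it makes SPARQL queries nearly impossible to
write by hand:

```sparql
?gene SIO:SIO_000062 <http://lsrn.org/KEGG_PATHWAY:hsa00232>
```

is meaningless to read and absurd to remember. `sparqlcompose` solves this
at the tool level. It is a completion engine for SPARQL SELECT queries
aimed at query builders, notebook users and service developers working
against opaque-identifier vocabularies (SIO-style predicates, KEGG-style
record individuals):

* **Ontology indexing** (`index_ontology`, `load_json_index`): terms from
  RDF/XML or Turtle documents are indexed by their labels and
  descriptions, with the `xml:lang` tag of each literal recorded, so one
  URI is findable under "has participant" and "hat Beteiligten" alike.
  Ontologies named in a query's `FROM` clause are indexed on the fly
  (`resolve_from_clauses`).
* **Partial parsing** (`parse_partial`): a total tokenizer and a
  state-machine parser recover, from an incomplete query and a cursor
  offset, the grammatical position being completed (keyword, prefix,
  variable, subject, predicate, object), the declared prefixes and
  variables, and the triple patterns typed so far.
* **Ranked suggestion** (`suggest`, `apply_suggestion`): completions are
  matched case-insensitively in four grades (label prefix > word prefix >
  label substring > description substring), ranked, and — on acceptance —
  spliced into the query as a prefixed name or `<IRI>`, replacing the
  human-readable text with the opaque URI.
* **Service-aware matchmaking** (`sadi_registry`, `propagate_types`,
  `annotate_predicates`): with a registry of SADI-style services (each
  consuming an input class and attaching a property), predicates that a
  service can generate for the current subject are highlighted, and the
  service's output class is propagated onto the object variable, so the
  *next* clause already knows what `?gene` will contain.

## Worked example

All inputs are generated, deterministic fixtures (no downloads):

```r
library(sparqlcompose)
fx <- walkthrough_fixture()   # Turtle/RDF-XML ontologies, registry, namespaces
ix <- walkthrough_index(fx)
ix
#> <term_index> 9 terms (5 properties, 1 individuals, 3 classes), 6 namespaces

q <- "SELECT ?gene WHERE { ?gene parti"
for (s in suggest(q, nchar(q), ix)) print(s)
#> <suggestion> [property] has participant -> <http://semanticscience.org/resource/SIO_000132>
#> <suggestion> [property] is participant in -> <http://semanticscience.org/resource/SIO_000062>
```

Typing `parti` in predicate position offers exactly the two participation
predicates, each carrying its description. With a known individual as
subject and a service registry, the serviceable predicate is highlighted
(`*`) and ranked first:

```r
reg <- read_registry(fx$registry_json)
q2 <- "SELECT ?gene WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> parti"
for (s in suggest(q2, nchar(q2), ix, reg)) print(s)
#> <suggestion> [property] * has participant -> <http://semanticscience.org/resource/SIO_000132>
#> <suggestion> [property] is participant in -> <http://semanticscience.org/resource/SIO_000062>

apply_suggestion(q2, nchar(q2), suggest(q2, nchar(q2), ix, reg)[[1]])$text
#> "SELECT ?gene WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> <http://semanticscience.org/resource/SIO_000132> "
```

The accepted label has been rewritten to its opaque URI. Because the
pathway-consuming service declares a gene-record output class, `?gene` is
now typed, and a gene-consuming service's predicate will be highlighted in
the following clause. A German user typing `Bet` instead of `parti` is
offered `hat Beteiligten` — a different label for the same URI — and ends
up with a byte-identical query.

A command-line interface (`inst/scripts/sparql-complete`) wraps the same
functions: `index` builds a JSON preload index from ontology files,
`complete` prints the suggestion list for a query and cursor as JSON, and
`repl` is a scriptable line-oriented composer.

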