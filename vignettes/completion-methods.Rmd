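---
title: "How sparqlcompose suggests: indexing, partial parsing and service matchmaking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How sparqlcompose suggests: indexing, partial parsing and service matchmaking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparqlcompose)
```

This vignette explains the model behind the package: what is indexed, how
an incomplete query is interpreted, how suggestions are graded and ranked,
what the service registry adds, and where the deliberate simplifications
lie. Nothing here states an empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The completion model

A completion request is a pair *(query text, cursor offset)*. Three
components cooperate:

1. a **term index** mapping URIs to sets of `(label, language-tag)` and
   `(description, language-tag)` pairs, plus a namespace table;
2. a **partial parser** that reads the text *before* the cursor and
   reports the grammatical position being completed together with the
   query context (prefixes, variables, triple patterns so far);
3. a **suggestion engine** that dispatches on the position, matches the
   token being typed against the index, and ranks the result.

Accepting a suggestion splices its insertion text into the query. For
ontology terms the insertion is the opaque URI — as a prefixed name when a
declared `PREFIX` covers it, otherwise `<…>` — so the human-readable label
the user typed never survives into the final query. This is what makes the
engine language-neutral: two users typing labels in different languages
converge on byte-identical queries.

## Indexing: labels, languages, fallbacks

Terms are harvested from RDF documents (Turtle and RDF/XML). Declared
object/datatype/annotation properties become `property` terms, declared
classes `class` terms, and subjects typed with a non-meta class become
`individual` terms whose `rdf:type` assertions are retained for registry
matchmaking. Documents that merely add labels to already-indexed URIs
(label-extension ontologies, e.g. a German translation file) extend the
existing terms; labels are unioned, never replaced, and re-indexing the
same document is idempotent.

Which annotation properties count as labels is configurable. The defaults
are `rdfs:label`, `skos:prefLabel` and `dc:title` for labels, and
`rdfs:comment`, `dc:description` and `skos:definition` for descriptions.
These lists are a design choice, not a standard: most biomedical
vocabularies use `rdfs:label`/`rdfs:comment`, and the remaining entries
cover the common alternatives without dragging in full annotation-property
reasoning.

A term with no label at all is still findable under its URI *local name*
(the segment after the last `#`, `/` or `:`), recorded as an untagged
label. This fallback is what surfaces naming collisions honestly: an
unlabeled `…#isEncodedBy` and a labeled "is encoded by" are distinct URIs
with indistinguishable surface forms, and both are shown — the engine
never infers equivalence between vocabularies.

Matching is case-insensitive with four grades:

| grade | rule |
|---|---|
| 1 | a label starts with the typed text |
| 2 | a whitespace-delimited word of a label starts with it |
| 3 | a label contains it |
| 4 | a description contains it |

A language filter excludes labels carrying a *different* non-empty tag but
always admits untagged labels, because most ontologies omit `xml:lang`
entirely and excluding untagged labels would make an English-language
session unusable. Each URI appears at most once, represented by its
best-matching label; ties within a grade break lexicographically on the
case-folded label and then the URI, using byte order (`method = "radix"`)
so that rankings do not depend on the session locale.

## Partial parsing

The tokenizer is total: any string lexes, with unclassifiable runs typed
`unknown`, so a half-typed word is simply the current token. The parser is
a state machine over the supported SELECT subset — `PREFIX*`,
`SELECT (DISTINCT) vars|*`, `FROM*`, and a WHERE group of triple patterns
with `.` closing a pattern, `;` repeating the subject and `,` repeating
subject and predicate; `OPTIONAL`/`UNION` groups parse as nested graph
patterns and `FILTER` expressions are skipped as opaque. This subset was
chosen to cover what a completion assistant is actually used for;
`CONSTRUCT`/`ASK`, property paths, subqueries and aggregation are out of
scope.

Two choices matter for stability:

* **Only the text before the cursor is parsed.** Edits after the cursor
  can never change the reported context, and a cursor in the middle of a
  token sees the token's typed prefix.
* **The current token is the maximal non-punctuation token ending exactly
  at the cursor.** A cursor after whitespace has an empty current token
  (the "what can come next?" case).

The position enum has no value for states where only punctuation can
follow (after `WHERE` before `{`, after a completed object before its
separator). These map to the nearest enum value with an empty
expected-category set, and the engine emits no suggestions there — that
keeps the invariant that every emitted suggestion, once applied, re-lexes
in the position it was offered for. The test suite checks the reported
position against an independently written grammar acceptor over every
viable query prefix of up to eight tokens from a small vocabulary. The
soundness property is stated directionally: the reported position's token
role must be among the roles the grammar admits, and where exactly one
role continues it must be the reported one. A strict biconditional is not
attainable with a single reported position, because several states
legitimately admit two roles (after `SELECT ?x`, both another variable
and `FROM`/`WHERE`).

## Ranking

Suggestions are ordered by tier, then grade, then case-folded display
text, then URI:

1. registry-highlighted (serviceable) properties,
2. declared variables (in subject/object position),
3. everything else by match grade 1 < 2 < 3 < 4.

Variables rank above fresh terms because re-use of an already-declared
variable is almost always what the author wants; highlighted properties
rank above everything because a service is known to be able to generate
them. The list is truncated to `max_suggestions` (default 10, the size of
a comfortable dropdown). Duplicate labels from distinct URIs are *not*
deduplicated, by design.

## The service registry

A SADI-style service record is `(input class, attached property, output
class)`. Three operations use it:

* `available_properties`: the properties attached by services whose input
  class is in the given set — **exact IRI matching**. Real SADI
  matchmaking reasons over OWL class expressions; exact matching is a
  deliberate simplification that keeps the module testable without a
  reasoner and is flagged as such.
* `propagate_types`: the fixpoint of "if the subject of a triple is an
  individual of class *T* (or a variable already assigned *T*) and a
  record *(T, p, O)* exists, assign *O* to the object variable".
  Assignments only grow, so termination is immediate; correctness is
  checked against a from-scratch closure computation on random instances.
* `annotate_predicates`: highlights serviceable predicate suggestions and
  *removes* properties known only from the registry when no service
  accepts the current subject. Ontology-indexed properties are never
  removed, only left unhighlighted — the registry refines, it does not
  censor, what the loaded vocabularies offer. When the subject's classes
  are unknown, nothing is filtered or highlighted: ignorance vetoes
  nothing.

An engine call with no registry behaves identically to one with an empty
registry.

## Fixtures: what they emulate, and what they do not

The walkthrough fixture is a miniature opaque-identifier vocabulary built
for end-to-end sessions: two participation predicates with English labels
and descriptions, a description-less "is encoded by" colliding with an
unlabeled `isEncodedBy` from a second vocabulary, a codes-for predicate
(its URI is a documented synthetic placeholder, `SIO_999999`; no test
asserts its value), a KEGG-style pathway individual with English and
German labels, a German label-extension ontology, and a two-service
registry chaining pathway → genes → proteins. The same content is emitted
in Turtle and RDF/XML for parser coverage, byte-identically across
builds. Description strings are deliberately synthetic: tests assert the
presence or absence of descriptions, never their wording.

The random generator (`random_fixture`) produces seed-deterministic
ontologies with configurable term counts, per-language pseudo-word labels
and optional label collisions. It emulates the *structure* of real
vocabularies — multilingual labels, typed individuals, collisions — but
not their scale (hundreds of terms, not hundreds of thousands), their
label idiosyncrasies (punctuation, markup, very long definitions), blank
nodes, or OWL class expressions. Passing tests therefore demonstrate the
engine's logic, not its performance or robustness on arbitrary real-world
OWL.

## Numerical and degenerate-input choices

* Offsets are 0-based, half-open, in characters (UTF-8 safe).
* Keywords match case-insensitively and are suggested upper-case; `a` is
  accepted as predicate shorthand for `rdf:type`.
* The empty query matches every term at grade 1, ordered by display
  label — the "show me everything" browse case.
* An unparseable `FROM` ontology logs a warning and is skipped; a fetch is
  attempted once per index. Fetching is pluggable and the default fetcher
  resolves local paths and `file://` IRIs only.
* Parse errors carry the character offset of the first offending token;
  a prefixed name with an undeclared prefix inside a pattern is an error
  (prefix expansion must always yield absolute IRIs).

## Problem sizes

The property suites run at sizes chosen to exercise every code path while
keeping a full check quick: the grammar oracle enumerates all viable
prefixes up to eight tokens (about 1,600, of which about 1,100 end in a
content position), type propagation is compared to the brute-force
closure on 200 random instances of up to 10 triples and 10 records, and
index invariants run over 100 random ontologies of up to ~10 terms in one
or two languages. `scripts/acceptance.R` re-runs all of these from
scratch and reports the agreement fractions it measures.

## Known limitations

* No OWL reasoning of any kind: no subsumption in matchmaking, no
  inverse-property inference, no equivalence merging of colliding terms.
* No fuzzy matching or stemming; a user must hit a prefix, word or
  substring of an existing label.
* The SPARQL subset excludes solution modifiers, property paths and
  subqueries; `FILTER` contents get no completion.
* The composed query is rendered with opaque URIs — the tool does not
  translate a finished query back into natural language.
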