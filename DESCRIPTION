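Package: sparqlcompose
Title: Context-Sensitive Multilingual Completion for SPARQL Query Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A language-neutral completion engine for SPARQL SELECT queries.
    Ontology terms are indexed by their language-tagged labels and
    descriptions, so that a user can type a human-readable name in any
    language for which labels exist and have it rewritten into the
    corresponding opaque URI. A tokenizer and partial parser determine the
    grammatical position at the cursor of an incomplete query, and the
    suggestion engine produces ranked, context-sensitive completions
    (keywords, namespace prefixes, previously declared variables,
    properties, individuals and classes). An optional semantic-web-service
    registry in the SADI style filters and highlights predicate suggestions
    by service availability and propagates service output types onto query
    variables across clauses. Includes deterministic fixture generators and
    a command-line interface for indexing ontologies and completing queries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
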