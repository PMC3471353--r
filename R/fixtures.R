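# Deterministic fixture generators. Every test input — ontologies, the
# service registry, the namespace preload — is generated here; nothing is
# downloaded. The walkthrough fixture emulates a small opaque-identifier
# vocabulary (SIO-style predicates, a KEGG-style pathway individual) with
# English and German labels, sufficient to drive a complete composition
# session in either language.

WALKTHROUGH_SIO <- "http://semanticscience.org/resource/"
WALKTHROUGH_GEN <- "http://example.org/genetics#"
WALKTHROUGH_LSRN <- "http://example.org/lsrn/"
WALKTHROUGH_PATHWAY <- "http://lsrn.org/KEGG_PATHWAY:hsa00232"
WALKTHROUGH_PATHWAY_CLASS <- paste0(WALKTHROUGH_LSRN, "KEGG_PATHWAY_Record")
WALKTHROUGH_GENE_CLASS <- paste0(WALKTHROUGH_LSRN, "KEGG_GENE_Record")
WALKTHROUGH_PROTEIN_CLASS <- paste0(WALKTHROUGH_LSRN, "PROTEIN_Record")
# The codes-for predicate has no published opaque identifier in our
# vocabulary; SIO_999999 is a documented synthetic placeholder and nothing
# may assert its value.
WALKTHROUGH_CODES_FOR <- paste0(WALKTHROUGH_SIO, "SIO_999999")

walkthrough_core_ttl <- function() {
  paste(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix sio: <http://semanticscience.org/resource/> .",
    "@prefix gen: <http://example.org/genetics#> .",
    "@prefix lsrn: <http://example.org/lsrn/> .",
    "",
    "sio:SIO_000062 a owl:ObjectProperty ;",
    "    rdfs:label \"is participant in\"@en ;",
    "    rdfs:comment \"Relates an entity to a process it takes part in (synthetic fixture description).\"@en .",
    "",
    "sio:SIO_000132 a owl:ObjectProperty ;",
    "    rdfs:label \"has participant\"@en ;",
    "    rdfs:comment \"Relates a process to an entity that takes part in it (synthetic fixture description).\"@en .",
    "",
    "sio:SIO_010079 a owl:ObjectProperty ;",
    "    rdfs:label \"is encoded by\"@en .",
    "",
    "gen:isEncodedBy a owl:ObjectProperty .",
    "",
    "sio:SIO_999999 a owl:ObjectProperty .",
    "",
    "lsrn:KEGG_PATHWAY_Record a owl:Class ;",
    "    rdfs:label \"KEGG pathway record\"@en .",
    "",
    "lsrn:KEGG_GENE_Record a owl:Class ;",
    "    rdfs:label \"KEGG gene record\"@en .",
    "",
    "lsrn:PROTEIN_Record a owl:Class ;",
    "    rdfs:label \"protein record\"@en .",
    "",
    sep = "\n")
}

walkthrough_core_owl <- function() {
  paste(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "         xmlns:owl=\"http://www.w3.org/2002/07/owl#\">",
    "  <owl:ObjectProperty rdf:about=\"http://semanticscience.org/resource/SIO_000062\">",
    "    <rdfs:label xml:lang=\"en\">is participant in</rdfs:label>",
    "    <rdfs:comment xml:lang=\"en\">Relates an entity to a process it takes part in (synthetic fixture description).</rdfs:comment>",
    "  </owl:ObjectProperty>",
    "  <owl:ObjectProperty rdf:about=\"http://semanticscience.org/resource/SIO_000132\">",
    "    <rdfs:label xml:lang=\"en\">has participant</rdfs:label>",
    "    <rdfs:comment xml:lang=\"en\">Relates a process to an entity that takes part in it (synthetic fixture description).</rdfs:comment>",
    "  </owl:ObjectProperty>",
    "  <owl:ObjectProperty rdf:about=\"http://semanticscience.org/resource/SIO_010079\">",
    "    <rdfs:label xml:lang=\"en\">is encoded by</rdfs:label>",
    "  </owl:ObjectProperty>",
    "  <owl:ObjectProperty rdf:about=\"http://example.org/genetics#isEncodedBy\"/>",
    "  <owl:ObjectProperty rdf:about=\"http://semanticscience.org/resource/SIO_999999\"/>",
    "  <owl:Class rdf:about=\"http://example.org/lsrn/KEGG_PATHWAY_Record\">",
    "    <rdfs:label xml:lang=\"en\">KEGG pathway record</rdfs:label>",
    "  </owl:Class>",
    "  <owl:Class rdf:about=\"http://example.org/lsrn/KEGG_GENE_Record\">",
    "    <rdfs:label xml:lang=\"en\">KEGG gene record</rdfs:label>",
    "  </owl:Class>",
    "  <owl:Class rdf:about=\"http://example.org/lsrn/PROTEIN_Record\">",
    "    <rdfs:label xml:lang=\"en\">protein record</rdfs:label>",
    "  </owl:Class>",
    "</rdf:RDF>",
    sep = "\n")
}

walkthrough_kegg_ttl <- function() {
  paste(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix lsrn: <http://example.org/lsrn/> .",
    "",
    "<http://lsrn.org/KEGG_PATHWAY:hsa00232> a lsrn:KEGG_PATHWAY_Record ;",
    "    rdfs:label \"human caffeine metabolism pathway\"@en ;",
    "    rdfs:comment \"KEGG pathway hsa00232 (synthetic fixture description).\"@en .",
    "",
    sep = "\n")
}

walkthrough_props_de_ttl <- function() {
  paste(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix sio: <http://semanticscience.org/resource/> .",
    "",
    "sio:SIO_000132 rdfs:label \"hat Beteiligten\"@de .",
    "",
    "sio:SIO_999999 rdfs:label \"codiert für\"@de .",
    "",
    "<http://lsrn.org/KEGG_PATHWAY:hsa00232> rdfs:label \"Stoffwechselweg Koffein menschlichen\"@de .",
    "",
    sep = "\n")
}

walkthrough_registry_json <- function() {
  paste(
    "{",
    "  \"services\": [",
    "    {",
    "      \"id\": \"service-pathway-participants\",",
    paste0("      \"input_class\": \"", WALKTHROUGH_PATHWAY_CLASS, "\","),
    paste0("      \"property\": \"", WALKTHROUGH_SIO, "SIO_000132\","),
    paste0("      \"output_class\": \"", WALKTHROUGH_GENE_CLASS, "\""),
    "    },",
    "    {",
    "      \"id\": \"service-gene-products\",",
    paste0("      \"input_class\": \"", WALKTHROUGH_GENE_CLASS, "\","),
    paste0("      \"property\": \"", WALKTHROUGH_CODES_FOR, "\","),
    paste0("      \"output_class\": \"", WALKTHROUGH_PROTEIN_CLASS, "\""),
    "    }",
    "  ]",
    "}",
    sep = "\n")
}

walkthrough_namespaces_json <- function() {
  paste(
    "{",
    "  \"namespaces\": [",
    "    {\"prefix\": \"SIO\", \"uri\": \"http://semanticscience.org/resource/\", \"name\": \"Semanticscience Integrated Ontology\"},",
    "    {\"prefix\": \"kegg\", \"uri\": \"http://lsrn.org/KEGG_PATHWAY:\", \"name\": \"KEGG Pathway identifiers (Kyoto Encyclopedia of Genes and Genomes)\"},",
    "    {\"prefix\": \"gen\", \"uri\": \"http://example.org/genetics#\", \"name\": \"genetics vocabulary (synthetic fixture)\"},",
    "    {\"prefix\": \"rdf\", \"uri\": \"http://www.w3.org/1999/02/22-rdf-syntax-ns#\", \"name\": \"RDF vocabulary\"},",
    "    {\"prefix\": \"rdfs\", \"uri\": \"http://www.w3.org/2000/01/rdf-schema#\", \"name\": \"RDF Schema vocabulary\"},",
    "    {\"prefix\": \"owl\", \"uri\": \"http://www.w3.org/2002/07/owl#\", \"name\": \"OWL vocabulary\"}",
    "  ],",
    "  \"terms\": []",
    "}",
    sep = "\n")
}

#' Write the canonical walkthrough fixture
#'
#' Emits, into `dir`: an English core ontology (Turtle and an RDF/XML
#' variant) declaring the participation predicates `SIO_000062` /
#' `SIO_000132`, the description-less `SIO_010079` ("is encoded by") and a
#' colliding second-vocabulary `isEncodedBy`, a placeholder codes-for
#' predicate and the pathway/gene/protein record classes; a KEGG-style
#' pathway individual with an English label; a German label-extension
#' ontology; a two-service registry (pathway -> genes, gene -> proteins);
#' and a JSON namespace preload. Output is byte-identical across calls.
#'
#' @param dir Output directory (created if needed).
#' @return Named list of file paths: `core_ttl`, `core_owl`, `kegg_ttl`,
#'   `props_de_ttl`, `registry_json`, `namespaces_json`.
#' @export
walkthrough_fixture <- function(dir = tempfile("walkthrough")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    core_ttl = c("core.ttl", walkthrough_core_ttl()),
    core_owl = c("core.owl", walkthrough_core_owl()),
    kegg_ttl = c("kegg.ttl", walkthrough_kegg_ttl()),
    props_de_ttl = c("props.de.ttl", walkthrough_props_de_ttl()),
    registry_json = c("registry.json", walkthrough_registry_json()),
    namespaces_json = c("namespaces.json", walkthrough_namespaces_json())
  )
  out <- list()
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]][1])
    con <- file(path, open = "wb")
    writeLines(enc2utf8(files[[nm]][2]), con, useBytes = TRUE)
    close(con)
    out[[nm]] <- path
  }
  out
}

#' Build the walkthrough term index
#'
#' Convenience wrapper: indexes the English core ontology and the pathway
#' individual and loads the namespace preload; optionally also merges the
#' German label-extension ontology.
#'
#' @param fixture Output of [walkthrough_fixture()] (default: a fresh one).
#' @param german Merge the German label extensions too?
#' @param rdfxml Index the RDF/XML variant of the core ontology instead of
#'   the Turtle one.
#' @return A `term_index`.
#' @export
walkthrough_index <- function(fixture = walkthrough_fixture(),
                              german = FALSE, rdfxml = FALSE) {
  index <- load_json_index(fixture$namespaces_json)
  index <- index_ontology(if (rdfxml) fixture$core_owl else fixture$core_ttl,
                          index)
  index <- index_ontology(fixture$kegg_ttl, index)
  if (german) index <- index_ontology(fixture$props_de_ttl, index)
  index
}

#' Specification for a random fixture ontology
#'
#' @param n_properties,n_individuals,n_classes Term counts (>= 0).
#' @param languages Language tags for which labels are generated.
#' @param collision_labels Label texts attached verbatim to the first two
#'   generated properties each (requires `n_properties >= 2`).
#' @param seed Integer seed; the same spec yields byte-identical output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_properties = 5, n_individuals = 3, n_classes = 2,
                         languages = "en", collision_labels = character(),
                         seed = 1) {
  stopifnot(n_properties >= 0, n_individuals >= 0, n_classes >= 0)
  if (length(collision_labels) > 0 && n_properties < 2) {
    stop("collision labels need at least two properties")
  }
  structure(list(n_properties = n_properties, n_individuals = n_individuals,
                 n_classes = n_classes, languages = languages,
                 collision_labels = collision_labels, seed = seed),
            class = "fixture_spec")
}

# Pseudo-random pronounceable words, language-flavored so that en/de label
# sets are disjoint in practice.
rand_word <- function(lang) {
  syll <- switch(lang,
    de = c("schaf", "wurz", "stoff", "zell", "bahn", "kern", "licht", "weg"),
    fr = c("lume", "voie", "gene", "mer", "fleur", "roche", "vent", "pont"),
    c("path", "gene", "cell", "meta", "lysis", "prot", "flux", "zyme"))
  paste0(paste(sample(syll, 2, replace = TRUE), collapse = ""),
         sample(99, 1))
}

#' Generate a random ontology document
#'
#' Emits a Turtle ontology with `n_properties` object properties,
#' `n_individuals` named individuals and `n_classes` classes, each labeled
#' with a pseudo-random word per requested language; collision labels are
#' duplicated across the first two properties. Deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional file path to write to.
#' @return The Turtle text (invisibly when `path` is given).
#' @export
random_fixture <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  txt <- with_preserved_seed(spec$seed, {
    lines <- c(
      "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
      "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
      "@prefix ex: <http://example.org/random#> .",
      "")
    emit_term <- function(local, decl, n_labels_langs, extra_labels = character()) {
      labels <- c(
        vapply(n_labels_langs, function(lg)
          sprintf("    rdfs:label \"%s\"@%s ;", rand_word(lg), lg), ""),
        vapply(extra_labels, function(lab)
          sprintf("    rdfs:label \"%s\" ;", lab), ""))
      block <- c(sprintf("ex:%s a %s ;", local, decl), labels)
      block[length(block)] <- sub(" ;$", " .", block[length(block)])
      c(block, "")
    }
    for (k in seq_len(spec$n_classes)) {
      lines <- c(lines, emit_term(sprintf("Class%03d", k), "owl:Class",
                                  spec$languages))
    }
    for (k in seq_len(spec$n_properties)) {
      extra <- if (k <= 2) spec$collision_labels else character()
      lines <- c(lines, emit_term(sprintf("Prop%03d", k), "owl:ObjectProperty",
                                  spec$languages, extra))
    }
    for (k in seq_len(spec$n_individuals)) {
      decl <- if (spec$n_classes > 0) {
        sprintf("ex:Class%03d", ((k - 1) %% spec$n_classes) + 1)
      } else "owl:NamedIndividual"
      lines <- c(lines, emit_term(sprintf("Ind%03d", k), decl,
                                  spec$languages))
    }
    paste(lines, collapse = "\n")
  })
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    writeLines(enc2utf8(txt), con, useBytes = TRUE)
    close(con)
    return(invisible(txt))
  }
  txt
}
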