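# Language-aware term index: the lookup structure behind every completion.
# Terms (properties, individuals, classes) are keyed by URI and carry sets of
# (text, language-tag) labels and descriptions; namespaces are an ordered
# list of (prefix, IRI, display name) entries.

META_PROPERTY_TYPES <- c(
  "http://www.w3.org/2002/07/owl#ObjectProperty",
  "http://www.w3.org/2002/07/owl#DatatypeProperty",
  "http://www.w3.org/2002/07/owl#AnnotationProperty",
  "http://www.w3.org/1999/02/22-rdf-syntax-ns#Property"
)
META_CLASS_TYPES <- c(
  "http://www.w3.org/2002/07/owl#Class",
  "http://www.w3.org/2000/01/rdf-schema#Class"
)
IRI_NAMED_INDIVIDUAL <- "http://www.w3.org/2002/07/owl#NamedIndividual"
IRI_ONTOLOGY <- "http://www.w3.org/2002/07/owl#Ontology"

#' Create an empty term index
#'
#' @return An object of class `term_index` with no terms and no namespaces.
#' @seealso [index_ontology()], [match_terms()], [load_json_index()]
#' @export
term_index <- function() {
  structure(list(terms = list(), namespaces = list()), class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  kinds <- vapply(x$terms, function(t) t$kind, "")
  cat("<term_index> ", length(x$terms), " terms (",
      sum(kinds == "property"), " properties, ",
      sum(kinds == "individual"), " individuals, ",
      sum(kinds == "class"), " classes), ",
      length(x$namespaces), " namespaces\n", sep = "")
  invisible(x)
}

#' Number of terms / namespaces in an index
#' @param index A `term_index`.
#' @return Integer count.
#' @export
n_terms <- function(index) length(index$terms)

#' @rdname n_terms
#' @export
n_namespaces <- function(index) length(index$namespaces)

#' Retrieve one indexed term by URI
#' @param index A `term_index`.
#' @param uri Absolute term IRI.
#' @return The term (a list with `uri`, `kind`, `labels`, `descriptions`,
#'   `types`) or `NULL`.
#' @export
get_term <- function(index, uri) index$terms[[uri]]

new_term <- function(uri, kind) {
  list(uri = uri, kind = kind,
       labels = empty_pairs(), descriptions = empty_pairs(),
       types = character())
}

# Merge term b into term a (same uri). Labels/descriptions/types take the
# union; an already-known kind is never overwritten by "individual" default.
merge_term <- function(a, b) {
  a$labels <- merge_pairs(a$labels, b$labels)
  a$descriptions <- merge_pairs(a$descriptions, b$descriptions)
  a$types <- union(a$types, b$types)
  if (a$kind == "individual" && b$kind != "individual" &&
      length(a$types) == 0) {
    a$kind <- b$kind
  }
  a
}

#' Add a namespace entry to an index
#'
#' @param index A `term_index`.
#' @param prefix Short name (no whitespace or colon; may be empty).
#' @param uri Absolute namespace IRI.
#' @param name Human-readable display name.
#' @return The updated index. Re-adding an existing prefix/IRI pair is a
#'   no-op.
#' @export
add_namespace <- function(index, prefix, uri, name = "") {
  stopifnot(is.character(uri), nzchar(uri))
  if (grepl("[\\s:]", prefix, perl = TRUE)) {
    stop("namespace prefix must not contain whitespace or ':'")
  }
  for (entry in index$namespaces) {
    if (entry$prefix == prefix && entry$uri == uri) return(index)
  }
  index$namespaces[[length(index$namespaces) + 1L]] <-
    list(prefix = prefix, uri = uri, name = name)
  index
}

#' Index an ontology document
#'
#' Reads an RDF document (Turtle or RDF/XML) and merges its declared
#' properties, classes and named individuals into a term index. Labels are
#' collected from `label_properties` with their language tags, descriptions
#' from `description_properties`. `rdf:type` assertions on individuals are
#' retained (for registry matchmaking). Indexing a document that only adds
#' labels to already-indexed URIs extends those terms in place; labels are
#' never replaced.
#'
#' Subjects that carry only annotations and are not yet indexed are recorded
#' as individuals: a thing that is labeled but undeclared is most often an
#' instance, and a later declaration upgrades the kind.
#'
#' @param document Path to an RDF file, a `file://` IRI, or a triple table
#'   from [read_rdf()].
#' @param index A `term_index` to merge into (default: a fresh one).
#' @param label_properties,description_properties Annotation property IRIs
#'   whose literal values become labels / descriptions.
#' @return The updated `term_index`.
#' @export
index_ontology <- function(document, index = term_index(),
                           label_properties = default_label_properties(),
                           description_properties = default_description_properties()) {
  triples <- if (is.data.frame(document)) document else read_rdf(document)
  if (nrow(triples) == 0) return(index)

  type_rows <- triples[triples$predicate == IRI_RDF_TYPE & !triples$is_literal, ]
  label_rows <- triples[triples$predicate %in% label_properties & triples$is_literal, ]
  desc_rows <- triples[triples$predicate %in% description_properties & triples$is_literal, ]

  subjects <- unique(c(type_rows$subject, label_rows$subject, desc_rows$subject))
  for (s in subjects) {
    if (!is_absolute_iri(s)) next
    types <- type_rows$object[type_rows$subject == s]
    if (IRI_ONTOLOGY %in% types) next
    kind <- if (any(types %in% META_PROPERTY_TYPES)) "property"
      else if (any(types %in% META_CLASS_TYPES)) "class"
      else "individual"
    inst_types <- setdiff(types, c(META_PROPERTY_TYPES, META_CLASS_TYPES,
                                   IRI_NAMED_INDIVIDUAL))
    if (kind != "individual") inst_types <- character()
    term <- new_term(s, kind)
    term$types <- inst_types
    lr <- label_rows[label_rows$subject == s, ]
    term$labels <- merge_pairs(empty_pairs(),
      data.frame(text = lr$object, lang = lr$lang, stringsAsFactors = FALSE))
    dr <- desc_rows[desc_rows$subject == s, ]
    term$descriptions <- merge_pairs(empty_pairs(),
      data.frame(text = dr$object, lang = dr$lang, stringsAsFactors = FALSE))
    if (kind == "individual" && length(types) == 0 &&
        nrow(term$labels) == 0 && nrow(term$descriptions) == 0) {
      next  # nothing indexable about this subject
    }
    existing <- index$terms[[s]]
    index$terms[[s]] <- if (is.null(existing)) term else merge_term(existing, term)
  }
  index
}

# Labels used for matching a term: its real labels, or the URI local name
# as an untagged fallback when it has none.
term_match_labels <- function(term) {
  if (nrow(term$labels) > 0) return(term$labels)
  data.frame(text = iri_local_name(term$uri), lang = "",
             stringsAsFactors = FALSE)
}

# Keep labels compatible with a language filter: untagged labels always
# qualify; tagged labels must match the filter's primary subtag.
filter_lang <- function(pairs, lang_filter) {
  if (is.null(lang_filter) || !nzchar(lang_filter)) return(pairs)
  primary <- function(x) sub("-.*", "", tolower(x))
  keep <- pairs$lang == "" | primary(pairs$lang) == primary(lang_filter)
  pairs[keep, , drop = FALSE]
}

# Match grade of query q (already casefolded) against one label:
# 1 label starts with q; 2 a whitespace-delimited word starts with q;
# 3 label contains q; NA no match. Empty q is grade 1.
label_grade <- function(label_fold, q) {
  if (!nzchar(q)) return(1L)
  if (startsWith(label_fold, q)) return(1L)
  words <- strsplit(label_fold, "\\s+")[[1]]
  if (any(startsWith(words, q))) return(2L)
  if (grepl(q, label_fold, fixed = TRUE)) return(3L)
  NA_integer_
}

# Display label for a term: prefer the filter language, then untagged, then
# English, then lexicographically first.
display_label <- function(term, lang_filter = NULL) {
  labs <- term_match_labels(term)
  pick <- function(rows) rows$text[order(casefold_q(rows$text), method = "radix")][1]
  if (!is.null(lang_filter) && nzchar(lang_filter)) {
    hit <- labs[tolower(labs$lang) == tolower(lang_filter), , drop = FALSE]
    if (nrow(hit) > 0) return(pick(hit))
  }
  hit <- labs[labs$lang == "", , drop = FALSE]
  if (nrow(hit) > 0) return(pick(hit))
  hit <- labs[tolower(sub("-.*", "", labs$lang)) == "en", , drop = FALSE]
  if (nrow(hit) > 0) return(pick(hit))
  pick(labs)
}

# Best description text for display under an optional language preference.
display_description <- function(term, lang_filter = NULL) {
  d <- term$descriptions
  if (nrow(d) == 0) return("")
  if (!is.null(lang_filter) && nzchar(lang_filter)) {
    hit <- d[tolower(d$lang) == tolower(lang_filter), , drop = FALSE]
    if (nrow(hit) > 0) return(hit$text[1])
  }
  hit <- d[d$lang == "", , drop = FALSE]
  if (nrow(hit) > 0) return(hit$text[1])
  d$text[1]
}

#' Match indexed terms against a typed query string
#'
#' Case-insensitive matching with four grades: 1 — a label starts with the
#' query; 2 — a whitespace-delimited word of a label starts with it; 3 — a
#' label contains it; 4 — a description contains it. A term with no labels is
#' matched through its URI local name. Each URI appears at most once,
#' represented by its best-matching label; results are ordered by grade,
#' then case-folded label, then URI. The empty query matches every term at
#' grade 1 (by its display label).
#'
#' @param query Typed text (may be empty).
#' @param index A `term_index`.
#' @param kind Optional filter: `"property"`, `"individual"` or `"class"`.
#' @param lang Optional language tag; labels carrying a different non-empty
#'   tag are excluded, untagged labels always qualify.
#' @return A data frame with columns `uri`, `kind`, `label`, `lang`,
#'   `grade`, `description`, ordered best match first.
#' @export
match_terms <- function(query, index, kind = NULL, lang = NULL) {
  q <- casefold_q(query)
  rows <- list()
  for (term in index$terms) {
    if (!is.null(kind) && term$kind != kind) next
    labs <- filter_lang(term_match_labels(term), lang)
    if (nrow(labs) == 0) next
    best_grade <- NA_integer_
    best_label <- NA_character_
    best_lang <- ""
    for (j in seq_len(nrow(labs))) {
      g <- label_grade(casefold_q(labs$text[j]), q)
      if (is.na(g)) next
      if (is.na(best_grade) || g < best_grade ||
          (g == best_grade && casefold_q(labs$text[j]) < casefold_q(best_label))) {
        best_grade <- g
        best_label <- labs$text[j]
        best_lang <- labs$lang[j]
      }
    }
    if (is.na(best_grade) && nzchar(q)) {
      descs <- filter_lang(term$descriptions, lang)
      if (nrow(descs) > 0 && any(grepl(q, casefold_q(descs$text), fixed = TRUE))) {
        best_grade <- 4L
        best_label <- display_label(term, lang)
        best_lang <- ""
      }
    }
    if (is.na(best_grade)) next
    rows[[length(rows) + 1L]] <- data.frame(
      uri = term$uri, kind = term$kind, label = best_label,
      lang = best_lang, grade = best_grade,
      description = display_description(term, lang),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(uri = character(), kind = character(),
                      label = character(), lang = character(),
                      grade = integer(), description = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$grade, casefold_q(out$label), out$uri, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match namespace entries against a typed query string
#'
#' Applies the same grading as [match_terms()] to each entry's prefix,
#' display name and namespace IRI (the best of the three wins).
#'
#' @param query Typed text (may be empty; empty matches everything).
#' @param index A `term_index`.
#' @return A data frame with columns `prefix`, `uri`, `name`, `grade`,
#'   ordered best match first.
#' @export
match_namespaces <- function(query, index) {
  q <- casefold_q(query)
  rows <- list()
  for (entry in index$namespaces) {
    fields <- c(entry$prefix, entry$name, entry$uri)
    grades <- vapply(fields, function(f) {
      if (!nzchar(f)) return(NA_integer_)
      label_grade(casefold_q(f), q)
    }, integer(1))
    if (all(is.na(grades))) next
    rows[[length(rows) + 1L]] <- data.frame(
      prefix = entry$prefix, uri = entry$uri, name = entry$name,
      grade = min(grades, na.rm = TRUE), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(prefix = character(), uri = character(),
                      name = character(), grade = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  key <- ifelse(nzchar(out$name), out$name, out$prefix)
  out <- out[order(out$grade, casefold_q(key), out$uri, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Map uri -> character vector of rdf:type class IRIs, for registry lookups.
individual_types <- function(index) {
  out <- list()
  for (term in index$terms) {
    if (length(term$types) > 0) out[[term$uri]] <- term$types
  }
  out
}
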