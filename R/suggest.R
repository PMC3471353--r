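# The suggestion engine: rank completions for a (query, cursor) pair and
# splice an accepted suggestion back into the query, rewriting
# human-readable labels into opaque URIs.

new_suggestion <- function(display, insertion, category,
                           description = "", target_uri = "",
                           grade = 1L, highlighted = FALSE) {
  structure(list(display = display, description = description,
                 insertion = insertion, target_uri = target_uri,
                 category = category, grade = as.integer(grade),
                 highlighted = isTRUE(highlighted)),
            class = "suggestion")
}

#' @export
print.suggestion <- function(x, ...) {
  cat(sprintf("<suggestion> [%s]%s %s -> %s\n", x$category,
              if (x$highlighted) " *" else "", x$display, x$insertion))
  invisible(x)
}

#' @export
format.suggestion <- function(x, ...) {
  sprintf("%-10s %s%s", x$category, x$display,
          if (nzchar(x$description)) paste0("  (", x$description, ")") else "")
}

# Insertion text for an indexed term: prefixed name when a declared prefix
# covers the URI and yields a lexable local part, otherwise <uri>.
term_insertion <- function(uri, prefixes) {
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    if (startsWith(uri, ns)) {
      local <- substr(uri, nchar(ns) + 1, nchar(uri))
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) && nzchar(pfx)) {
        return(paste0(pfx, ":", local))
      }
    }
  }
  paste0("<", uri, ">")
}

#' Produce ranked completions for a partial query
#'
#' Parses the query at the cursor and dispatches on the grammatical
#' position: keywords where a keyword is due, namespaces after `PREFIX` or
#' `FROM`, declared variables and named individuals (classes after `a`) in
#' subject/object position, and indexed properties in predicate position.
#' With a registry, predicate suggestions generated by services that can
#' accept the current subject are highlighted, registry-only properties
#' without such a service are dropped, and service output types propagate
#' onto variables across clauses.
#'
#' Ranking: highlighted (serviceable) properties first, then declared
#' variables, then term/namespace matches by match grade; ties break
#' lexicographically by display text, then URI.
#'
#' @param text Query text.
#' @param cursor 0-based cursor offset (default: end of text).
#' @param index A `term_index`.
#' @param registry Optional `sadi_registry`.
#' @param lang Optional language-tag preference for label matching.
#' @param max_suggestions Maximum list length (default 10).
#' @return A list of `suggestion` objects, best first.
#' @export
suggest <- function(text, cursor = nchar(text), index = term_index(),
                    registry = NULL, lang = NULL, max_suggestions = 10L) {
  ctx <- parse_partial(text, cursor)
  q <- ctx$current_token
  out <- list()
  add <- function(s) out[[length(out) + 1L]] <<- s

  keyword_suggestions <- function() {
    for (kw in ctx$expected_keywords) {
      if (!nzchar(q) || startsWith(casefold_q(kw), casefold_q(q))) {
        add(new_suggestion(display = kw, insertion = kw,
                           category = "keyword"))
      }
    }
  }
  variable_suggestions <- function() {
    vq <- sub("^[?$]", "", q)
    for (v in ctx$variables) {
      g <- label_grade(casefold_q(v), casefold_q(vq))
      if (!is.na(g)) {
        add(new_suggestion(display = paste0("?", v),
                           insertion = paste0("?", v),
                           category = "variable", grade = g))
      }
    }
  }
  term_suggestions <- function(kind, category) {
    hits <- match_terms(q, index, kind = kind, lang = lang)
    for (j in seq_len(nrow(hits))) {
      add(new_suggestion(display = hits$label[j],
                         description = hits$description[j],
                         insertion = term_insertion(hits$uri[j], ctx$prefixes),
                         target_uri = hits$uri[j],
                         category = category, grade = hits$grade[j]))
    }
  }
  namespace_suggestions <- function(mode) {
    nq <- if (mode == "iri") sub("^<", "", q) else q
    hits <- match_namespaces(nq, index)
    for (j in seq_len(nrow(hits))) {
      if (mode == "name" && !nzchar(hits$prefix[j])) next
      ins <- if (mode == "name") paste0(hits$prefix[j], ":")
        else paste0("<", hits$uri[j], ">")
      disp <- if (nzchar(hits$name[j])) hits$name[j] else hits$uri[j]
      add(new_suggestion(display = disp, description = hits$uri[j],
                         insertion = ins, target_uri = hits$uri[j],
                         category = "prefix", grade = hits$grade[j]))
    }
  }

  switch(ctx$position,
    KEYWORD = keyword_suggestions(),
    PREFIX_NAME = namespace_suggestions("name"),
    PREFIX_IRI = namespace_suggestions("iri"),
    FROM_IRI = namespace_suggestions("iri"),
    SELECT_VAR = { variable_suggestions(); keyword_suggestions() },
    SUBJECT = ,
    OBJECT = {
      if (length(ctx$expects) > 0) {
        variable_suggestions()
        if (!grepl("^[?$]", q)) {
          after_a <- FALSE
          if (ctx$position == "OBJECT" && length(ctx$triples) > 0) {
            last <- ctx$triples[[length(ctx$triples)]]
            after_a <- last$predicate$kind == "iri" &&
              last$predicate$value == IRI_RDF_TYPE
          }
          if (after_a) term_suggestions("class", "class")
          else term_suggestions("individual", "individual")
        }
      }
    },
    PREDICATE = {
      if (length(ctx$expects) > 0) {
        term_suggestions("property", "property")
        if (!is.null(registry)) {
          known <- vapply(out, function(s) s$target_uri, "")
          vq <- casefold_q(q)
          for (p in unique(registry$records$property)) {
            if (p %in% known || !is.null(get_term(index, p))) next
            g <- label_grade(casefold_q(iri_local_name(p)), vq)
            if (!is.na(g)) {
              add(new_suggestion(display = iri_local_name(p),
                                 insertion = term_insertion(p, ctx$prefixes),
                                 target_uri = p,
                                 category = "property", grade = g))
            }
          }
          assignment <- propagate_types(ctx, registry, individual_types(index))
          out <- annotate_predicates(out, ctx, registry, assignment,
                                     individual_types(index), index)
        }
      }
    }
  )

  rank_suggestions(out, max_suggestions)
}

rank_suggestions <- function(suggestions, max_suggestions) {
  if (length(suggestions) == 0) return(suggestions)
  tier <- vapply(suggestions, function(s) {
    if (s$highlighted) 0L else if (s$category == "variable") 1L else 2L
  }, 0L)
  grade <- vapply(suggestions, function(s) s$grade, 0L)
  disp <- casefold_q(vapply(suggestions, function(s) s$display, ""))
  uri <- vapply(suggestions, function(s) s$target_uri, "")
  ord <- order(tier, grade, disp, uri, method = "radix")
  suggestions <- suggestions[ord]
  suggestions[seq_len(min(length(suggestions), max_suggestions))]
}

#' Accept a suggestion: splice it into the query
#'
#' Replaces the span of the token being completed (or inserts at the cursor
#' when there is none) with the suggestion's insertion text plus one
#' trailing space, and places the cursor after it.
#'
#' @param text Query text.
#' @param cursor 0-based cursor offset.
#' @param s A `suggestion` produced by [suggest()] on the same `(text,
#'   cursor)`.
#' @return A list with `text` (rewritten query) and `cursor` (new offset).
#' @export
apply_suggestion <- function(text, cursor = nchar(text), s) {
  ctx <- parse_partial(text, cursor)
  span <- ctx$current_span
  before <- substr(text, 1, span[1])
  after <- substr(text, span[2] + 1, nchar(text))
  inserted <- paste0(s$insertion, " ")
  list(text = paste0(before, inserted, after),
       cursor = span[1] + nchar(inserted))
}

#' Fetch and index the ontologies named in FROM clauses
#'
#' Every IRI in the context's FROM clauses is fetched and merged into the
#' index via [index_ontology()]; each IRI is fetched at most once per index
#' (tracked on the returned object), and fetch or parse failures are logged
#' as warnings and skipped, never fatal.
#'
#' @param context A `completion_context`.
#' @param index A `term_index`.
#' @param fetcher Function mapping an IRI to a local path or document text;
#'   the default strips `file://` and reads local files.
#' @return The (possibly extended) `term_index`.
#' @export
resolve_from_clauses <- function(context, index,
                                 fetcher = default_fetcher) {
  loaded <- attr(index, "from_loaded") %||% character()
  for (iri in setdiff(context$from_iris, loaded)) {
    doc <- tryCatch(fetcher(iri), error = function(e) NULL)
    if (is.null(doc)) {
      warning("could not retrieve FROM ontology <", iri, ">; skipped")
      loaded <- union(loaded, iri)
      next
    }
    index <- tryCatch(index_ontology(doc, index), error = function(e) {
      warning("could not index FROM ontology <", iri, ">: ",
              conditionMessage(e))
      index
    })
    loaded <- union(loaded, iri)
  }
  attr(index, "from_loaded") <- loaded
  index
}

#' @rdname resolve_from_clauses
#' @param iri IRI to fetch.
#' @export
default_fetcher <- function(iri) {
  path <- sub("^file://", "", iri)
  if (!file.exists(path)) stop("not a local file: ", iri)
  path
}

#' Serialize a suggestion list to JSON
#'
#' Schema: an array of objects with keys `display`, `description`,
#' `insertion`, `uri`, `category`, `highlighted`.
#'
#' @param suggestions List of `suggestion` objects.
#' @return JSON text (a one-element character vector).
#' @export
suggestions_to_json <- function(suggestions) {
  items <- lapply(suggestions, function(s) {
    list(display = s$display, description = s$description,
         insertion = s$insertion, uri = s$target_uri,
         category = s$category, highlighted = s$highlighted)
  })
  as.character(jsonlite::toJSON(items, auto_unbox = TRUE, pretty = TRUE))
}
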