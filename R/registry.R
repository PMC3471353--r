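# SADI-style service registry: services consume instances of a declared
# input class and attach a declared property (optionally producing values of
# a declared output class). The registry drives predicate filtering and
# highlighting, and lets service output types propagate onto query
# variables across clauses. Matchmaking is by exact class IRI (no OWL
# subsumption).

#' Build a service registry from a record table
#'
#' @param records A data frame (or list of lists) with columns/fields `id`,
#'   `input_class`, `property` and `output_class` (`""` when the service
#'   declares none).
#' @return An object of class `sadi_registry`.
#' @export
sadi_registry <- function(records = NULL) {
  if (is.null(records)) {
    records <- data.frame(id = character(), input_class = character(),
                          property = character(), output_class = character(),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      data.frame(id = as.character(r$id %||% ""),
                 input_class = as.character(r$input_class %||% ""),
                 property = as.character(r$property %||% ""),
                 output_class = as.character(r$output_class %||% ""),
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("id", "input_class", "property", "output_class") %in%
                  names(records)))
  if (any(!nzchar(records$input_class)) || any(!nzchar(records$property))) {
    stop("every service record needs a non-empty input_class and property")
  }
  rownames(records) <- NULL
  structure(list(records = records), class = "sadi_registry")
}

#' @export
print.sadi_registry <- function(x, ...) {
  cat("<sadi_registry> ", nrow(x$records), " service records, ",
      length(unique(x$records$property)), " distinct properties\n", sep = "")
  invisible(x)
}

#' Read a registry from its JSON file
#'
#' Expected form: `{"services": [{"id": str, "input_class": str,
#' "property": str, "output_class": str}]}`.
#'
#' @param path Path to the JSON file (or JSON text).
#' @return A `sadi_registry`.
#' @export
read_registry <- function(path) {
  txt <- if (length(path) == 1 && file.exists(path)) {
    paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else paste(path, collapse = "\n")
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.list(parsed) || is.null(parsed$services)) {
    stop("registry JSON must be an object with a 'services' array")
  }
  sadi_registry(parsed$services)
}

#' Properties serviceable for a set of input classes
#'
#' @param input_classes Character vector of class IRIs.
#' @param registry A `sadi_registry`.
#' @return The attached-property IRIs of every record whose input class is
#'   in `input_classes` (exact match), in registry order, deduplicated.
#' @export
available_properties <- function(input_classes, registry) {
  if (is.null(registry) || length(input_classes) == 0) return(character())
  recs <- registry$records
  unique(recs$property[recs$input_class %in% input_classes])
}

#' Propagate service output types onto query variables
#'
#' Computes the fixpoint of: for a triple pattern `(s, p, o)` with `o` a
#' variable, if `s` is an individual of class `T` (from `individual_types`)
#' or a variable already assigned `T`, and some record `(T, p, O)` with a
#' non-empty output class exists, then `O` is added to the assignment of
#' `o`. Assignments only grow, so iteration terminates.
#'
#' @param context A `completion_context`.
#' @param registry A `sadi_registry` (or `NULL`).
#' @param individual_types Named list mapping individual IRIs to their class
#'   IRIs (`rdf:type` assertions from the index).
#' @return Named list: variable name -> character vector of class IRIs.
#'   Only variables occurring in the query appear.
#' @export
propagate_types <- function(context, registry, individual_types = list()) {
  assignment <- list()
  if (is.null(registry) || nrow(registry$records) == 0) return(assignment)
  recs <- registry$records
  recs <- recs[nzchar(recs$output_class), , drop = FALSE]
  if (nrow(recs) == 0) return(assignment)
  triples <- Filter(function(p) {
    p$predicate$kind == "iri" && p$object$kind == "variable" &&
      p$subject$kind %in% c("iri", "variable")
  }, context$triples)
  classes_of <- function(node) {
    if (node$kind == "iri") individual_types[[node$value]] %||% character()
    else assignment[[node$value]] %||% character()
  }
  repeat {
    changed <- FALSE
    for (p in triples) {
      subj_classes <- classes_of(p$subject)
      if (length(subj_classes) == 0) next
      hit <- recs$input_class %in% subj_classes & recs$property == p$predicate$value
      if (!any(hit)) next
      ov <- p$object$value
      new_classes <- union(assignment[[ov]] %||% character(),
                           recs$output_class[hit])
      if (length(new_classes) > length(assignment[[ov]] %||% character())) {
        assignment[[ov]] <- new_classes
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assignment
}

# Class IRIs of the subject of the clause currently being completed.
current_subject_classes <- function(context, assignment, individual_types) {
  triples <- context$triples
  if (length(triples) == 0) return(character())
  subj <- triples[[length(triples)]]$subject
  if (subj$kind == "iri") {
    individual_types[[subj$value]] %||% character()
  } else if (subj$kind == "variable") {
    assignment[[subj$value]] %||% character()
  } else {
    character()
  }
}

#' Filter and highlight predicate suggestions through the registry
#'
#' A property suggestion is highlighted when a service can accept the
#' current clause's subject (by its known classes) as input and attaches
#' that property. A property known only from the registry (absent from all
#' loaded ontologies) and not serviceable for those classes is removed;
#' ontology-indexed properties are never removed, only left unhighlighted.
#' When the subject's classes are unknown, nothing is filtered or
#' highlighted.
#'
#' @param suggestions List of suggestion objects at PREDICATE position.
#' @param context A `completion_context`.
#' @param registry A `sadi_registry` (or `NULL` for a no-op).
#' @param assignment Variable type assignment from [propagate_types()].
#' @param individual_types Named list of IRI -> class IRIs.
#' @param index Optional `term_index` used to decide which properties are
#'   ontology-known.
#' @return The annotated (possibly shorter) suggestion list.
#' @export
annotate_predicates <- function(suggestions, context, registry,
                                assignment = list(),
                                individual_types = list(),
                                index = NULL) {
  if (is.null(registry)) return(suggestions)
  classes <- current_subject_classes(context, assignment, individual_types)
  if (length(classes) == 0) return(suggestions)
  avail <- available_properties(classes, registry)
  registry_props <- unique(registry$records$property)
  keep <- list()
  for (s in suggestions) {
    if (s$category == "property" && nzchar(s$target_uri)) {
      if (s$target_uri %in% avail) {
        s$highlighted <- TRUE
      } else {
        ontology_known <- is.null(index) || !is.null(get_term(index, s$target_uri))
        registry_only <- s$target_uri %in% registry_props && !ontology_known
        if (registry_only) next
      }
    }
    keep[[length(keep) + 1L]] <- s
  }
  keep
}
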