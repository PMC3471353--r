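# JSON preload index: the interchange format for pre-indexed properties,
# individuals and namespaces.
#
#   {"namespaces": [{"prefix": str, "uri": str, "name": str}],
#    "terms": [{"uri": str, "kind": "property|individual|class",
#               "labels": [{"text": str, "lang": str}],
#               "descriptions": [{"text": str, "lang": str}],
#               "types": [str]}]}
#
# Unknown keys are ignored with a warning; a load/export cycle is the
# identity on the observable index content.

TERM_KINDS <- c("property", "individual", "class")

#' Load a term index from its JSON interchange form
#'
#' @param document JSON text, or a path to a JSON file.
#' @param index An existing `term_index` to merge into (default fresh).
#' @return A `term_index`.
#' @export
load_json_index <- function(document, index = term_index()) {
  txt <- if (length(document) == 1 && file.exists(document)) {
    paste(readLines(document, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    paste(document, collapse = "\n")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop("index JSON does not parse: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(parsed)) stop("index JSON root must be an object")
  known_root <- c("namespaces", "terms")
  extra <- setdiff(names(parsed), known_root)
  if (length(extra) > 0) {
    warning("ignoring unknown index keys: ", paste(extra, collapse = ", "))
  }
  for (k in seq_along(parsed$namespaces)) {
    nsx <- parsed$namespaces[[k]]
    path <- sprintf("namespaces[%d]", k)
    uri <- json_str(nsx, "uri", path, required = TRUE)
    index <- add_namespace(index,
                           prefix = json_str(nsx, "prefix", path),
                           uri = uri,
                           name = json_str(nsx, "name", path))
  }
  for (k in seq_along(parsed$terms)) {
    tj <- parsed$terms[[k]]
    path <- sprintf("terms[%d]", k)
    uri <- json_str(tj, "uri", path, required = TRUE)
    if (!is_absolute_iri(uri)) {
      stop("index JSON error at ", path, ".uri: not an absolute IRI")
    }
    kind <- json_str(tj, "kind", path, required = TRUE)
    if (!kind %in% TERM_KINDS) {
      stop("index JSON error at ", path, ".kind: must be one of ",
           paste(TERM_KINDS, collapse = "/"))
    }
    term <- new_term(uri, kind)
    term$labels <- json_pairs(tj$labels, paste0(path, ".labels"))
    term$descriptions <- json_pairs(tj$descriptions, paste0(path, ".descriptions"))
    term$types <- vapply(tj$types %||% list(), as.character, "")
    existing <- index$terms[[uri]]
    index$terms[[uri]] <- if (is.null(existing)) term else merge_term(existing, term)
  }
  index
}

json_str <- function(obj, key, path, required = FALSE) {
  v <- obj[[key]]
  if (is.null(v)) {
    if (required) stop("index JSON error at ", path, ".", key, ": missing")
    return("")
  }
  if (!is.character(v) && !is.numeric(v)) {
    stop("index JSON error at ", path, ".", key, ": not a string")
  }
  as.character(v)
}

json_pairs <- function(lst, path) {
  if (is.null(lst) || length(lst) == 0) return(empty_pairs())
  rows <- lapply(seq_along(lst), function(k) {
    item <- lst[[k]]
    data.frame(text = json_str(item, "text", sprintf("%s[%d]", path, k),
                               required = TRUE),
               lang = json_str(item, "lang", sprintf("%s[%d]", path, k)),
               stringsAsFactors = FALSE)
  })
  merge_pairs(empty_pairs(), do.call(rbind, rows))
}

#' Export a term index to its JSON interchange form
#'
#' @param index A `term_index`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
export_json_index <- function(index, path = NULL) {
  namespaces <- lapply(index$namespaces, function(e) {
    list(prefix = e$prefix, uri = e$uri, name = e$name)
  })
  uris <- sort(names(index$terms))
  terms <- lapply(uris, function(u) {
    t <- index$terms[[u]]
    list(uri = t$uri, kind = t$kind,
         labels = pairs_to_json(t$labels),
         descriptions = pairs_to_json(t$descriptions),
         types = as.list(t$types))
  })
  txt <- jsonlite::toJSON(list(namespaces = namespaces, terms = terms),
                          auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

pairs_to_json <- function(pairs) {
  lapply(seq_len(nrow(pairs)), function(j) {
    list(text = pairs$text[j], lang = pairs$lang[j])
  })
}
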