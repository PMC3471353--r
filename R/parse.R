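# Tokenizer and partial parser for an incomplete SPARQL SELECT query.
#
# Supported subset: PREFIX declarations, SELECT (DISTINCT) var-list or '*',
# FROM clauses, and a WHERE group of triple patterns with '.', ';', ','
# separators; OPTIONAL/UNION groups parse as nested basic graph patterns and
# FILTER expressions are skipped as opaque. The parser is total over text
# *before* the cursor only: everything after the cursor is ignored, so the
# reported context is stable under edits past the cursor.

SPARQL_KEYWORDS <- c("PREFIX", "SELECT", "DISTINCT", "WHERE", "FROM",
                     "NAMED", "FILTER", "OPTIONAL", "UNION", "LIMIT",
                     "OFFSET", "ORDER", "BY", "ASC", "DESC")

#' Tokenize (possibly incomplete) SPARQL text
#'
#' A total lexer: it never fails. Runs it cannot classify become `unknown`
#' tokens; keywords are recognized case-insensitively; an unterminated IRI
#' or string at the end of input is still emitted with its category.
#'
#' @param text Query text (any string, including empty).
#' @return A data frame with columns `text`, `category` (one of `keyword`,
#'   `variable`, `prefixed_name`, `iriref`, `literal`, `punctuation`,
#'   `unknown`) and 0-based half-open spans `start`, `end`.
#' @export
tokenize_sparql <- function(text) {
  empty <- data.frame(text = character(), category = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  # One alternation that matches at every position, so the matches tile the
  # input; order encodes lexing priority.
  master <- paste0(
    "<[^<>\\s]*>?",                                                 # IRI
    "|[?$](?:[A-Za-z_][A-Za-z0-9_]*)?",                             # variable
    '|"(?:[^"\\\\]|\\\\.)*(?:"(?:@[A-Za-z]+(?:-[A-Za-z0-9]+)*|\\^\\^\\S+)?)?',
    "|(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_.-]*",               # pname
    "|[+-]?[0-9]+(?:\\.[0-9]+)?",                                   # number
    "|[\\p{L}_][\\p{L}\\p{N}_]*",                                   # word
    "|#[^\n]*",                                                     # comment
    "|\\s+",
    "|.")
  m <- gregexpr(master, text, perl = TRUE)[[1]]
  pieces <- regmatches(text, list(m))[[1]]
  starts <- as.integer(m) - 1L
  rows <- vector("list", length(pieces))
  nrows <- 0L
  for (k in seq_along(pieces)) {
    piece <- pieces[k]
    first <- substr(piece, 1, 1)
    if (grepl("^\\s", piece) || first == "#") next
    cat <- NULL
    trailing_dots <- 0L
    if (first == "<") cat <- "iriref"
    else if (first %in% c("?", "$")) cat <- "variable"
    else if (first == '"' || grepl("^[+-]?[0-9]", piece)) cat <- "literal"
    else if (grepl(":", piece, fixed = TRUE)) {
      # trailing dots belong to statement punctuation, not the local name
      stripped <- sub("\\.+$", "", piece)
      trailing_dots <- nchar(piece) - nchar(stripped)
      piece <- stripped
      cat <- "prefixed_name"
    } else if (grepl("^[\\p{L}_]", piece, perl = TRUE)) {
      cat <- if (toupper(piece) %in% SPARQL_KEYWORDS || piece == "a")
        "keyword" else "unknown"
    } else {
      cat <- if (piece %in% c("{", "}", "(", ")", ".", ";", ",", "*"))
        "punctuation" else "unknown"
    }
    nrows <- nrows + 1L
    rows[[nrows]] <- data.frame(
      text = piece, category = cat, start = starts[k],
      end = starts[k] + nchar(piece), stringsAsFactors = FALSE)
    for (d in seq_len(trailing_dots)) {
      nrows <- nrows + 1L
      off <- starts[k] + nchar(piece) + d - 1L
      rows[[nrows]] <- data.frame(text = ".", category = "punctuation",
                                  start = off, end = off + 1L,
                                  stringsAsFactors = FALSE)
    }
  }
  if (nrows == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(nrows)])
  rownames(out) <- NULL
  out
}

parse_error <- function(msg, offset) {
  stop(structure(class = c("sparql_parse_error", "error", "condition"),
                 list(message = sprintf("%s (offset %d)", msg, offset),
                      call = NULL, offset = offset)))
}

node_var <- function(name) list(kind = "variable", value = sub("^[?$]", "", name))
node_iri <- function(iri) list(kind = "iri", value = iri)
node_lit <- function(text) list(kind = "literal", value = text)
node_missing <- function() list(kind = "missing", value = "")

new_pattern <- function() {
  list(subject = node_missing(), predicate = node_missing(),
       object = node_missing())
}

pattern_complete <- function(p) {
  p$subject$kind != "missing" && p$predicate$kind != "missing" &&
    p$object$kind != "missing"
}

#' Parse a partial SPARQL query at a cursor
#'
#' Determines the grammatical position being completed at `cursor` together
#' with everything declared before it: prefixes, variables, FROM IRIs and
#' the triple patterns of the WHERE group (the last pattern may be partially
#' filled). The current token is the maximal non-punctuation token whose
#' span ends exactly at the cursor; a cursor after whitespace has an empty
#' current token.
#'
#' @param text Query text.
#' @param cursor 0-based character offset, `0 <= cursor <= nchar(text)`;
#'   defaults to the end of the text.
#' @return A `completion_context`: a list with `position` (one of `KEYWORD`,
#'   `PREFIX_NAME`, `PREFIX_IRI`, `SELECT_VAR`, `FROM_IRI`, `SUBJECT`,
#'   `PREDICATE`, `OBJECT`), `current_token`, `current_span`, `prefixes`,
#'   `variables`, `triples`, `from_iris`, plus the completable token
#'   categories (`expects`) and valid keywords (`expected_keywords`) at the
#'   cursor.
#' @export
parse_partial <- function(text, cursor = nchar(text)) {
  if (cursor < 0 || cursor > nchar(text)) {
    stop("cursor out of range [0, ", nchar(text), "]")
  }
  pre <- substr(text, 1, cursor)
  toks <- tokenize_sparql(pre)

  current <- NULL
  ntok <- nrow(toks)
  if (ntok > 0 && toks$end[ntok] == cursor &&
      toks$category[ntok] != "punctuation") {
    current <- toks[ntok, ]
    toks <- toks[-ntok, , drop = FALSE]
  }

  ctx <- run_parser(toks)
  ctx$current_token <- if (is.null(current)) "" else current$text
  ctx$current_span <- if (is.null(current)) c(cursor, cursor)
    else c(current$start, current$end)
  ctx$cursor <- cursor
  ctx$text <- text
  class(ctx) <- "completion_context"
  ctx
}

#' @export
print.completion_context <- function(x, ...) {
  cat("<completion_context> position ", x$position,
      ", current token '", x$current_token, "'\n",
      "  prefixes: ", length(x$prefixes),
      " | variables: ", paste(x$variables, collapse = " "),
      " | triples: ", length(x$triples),
      " | FROM: ", length(x$from_iris), "\n", sep = "")
  invisible(x)
}

# State machine over completed tokens. States map onto the completion
# position plus the token categories that may legally continue.
run_parser <- function(toks) {
  state <- "start"
  prefixes <- character()
  variables <- character()
  triples <- list()
  from_iris <- character()
  pending_prefix <- NULL
  cur <- NULL          # in-progress triple pattern
  depth <- 0L          # '{' nesting depth inside WHERE
  filter_depth <- NA_integer_
  return_state <- "bgp_subject"

  add_var <- function(name) {
    name <- sub("^[?$]", "", name)
    if (nzchar(name) && !name %in% variables) variables <<- c(variables, name)
  }
  resolve <- function(tok) {
    if (tok$category == "iriref") {
      if (!grepl(">$", tok$text)) parse_error("unterminated IRI", tok$start)
      return(node_iri(substr(tok$text, 2, nchar(tok$text) - 1)))
    }
    if (tok$category == "variable") { add_var(tok$text); return(node_var(tok$text)) }
    if (tok$category == "literal") return(node_lit(tok$text))
    if (tok$category == "prefixed_name") {
      colon <- regexpr(":", tok$text, fixed = TRUE)
      pfx <- substr(tok$text, 1, colon - 1)
      if (!pfx %in% names(prefixes)) {
        parse_error(paste0("undeclared prefix '", pfx, ":'"), tok$start)
      }
      return(node_iri(paste0(prefixes[[pfx]],
                             substr(tok$text, colon + 1, nchar(tok$text)))))
    }
    if (tok$category == "keyword" && tok$text == "a") {
      return(node_iri(IRI_RDF_TYPE))
    }
    parse_error(paste0("unexpected token '", tok$text, "'"), tok$start)
  }
  close_triple <- function() {
    if (!is.null(cur) && cur$subject$kind != "missing") {
      triples[[length(triples) + 1L]] <<- cur
    }
    cur <<- NULL
  }

  for (k in seq_len(nrow(toks))) {
    tok <- toks[k, ]
    cat <- tok$category
    txt <- tok$text
    kw <- if (cat == "keyword") toupper(txt) else ""
    unexpected <- function() {
      parse_error(paste0("unexpected token '", txt, "' in state ", state),
                  tok$start)
    }

    if (!is.na(filter_depth)) {  # skipping an opaque FILTER expression
      if (cat == "punctuation" && txt == "(") filter_depth <- filter_depth + 1L
      if (cat == "punctuation" && txt == ")") {
        filter_depth <- filter_depth - 1L
        if (filter_depth == 0L) { filter_depth <- NA_integer_; state <- return_state }
      } else if (filter_depth == 0L) {
        unexpected()  # FILTER not followed by '('
      }
      if (cat == "variable") add_var(txt)
      next
    }

    state <- switch(state,
      start = {
        if (kw == "PREFIX") "prefix_name"
        else if (kw == "SELECT") "select_head"
        else unexpected()
      },
      prefix_name = {
        if (cat == "prefixed_name" && grepl(":$", txt)) {
          pending_prefix <- sub(":$", "", txt); "prefix_iri"
        } else unexpected()
      },
      prefix_iri = {
        if (cat == "iriref" && grepl(">$", txt)) {
          prefixes[[pending_prefix]] <- substr(txt, 2, nchar(txt) - 1)
          pending_prefix <- NULL
          "start"
        } else unexpected()
      },
      select_head = {
        if (kw == "DISTINCT") "select_head"
        else if (cat == "variable") { add_var(txt); "select_list" }
        else if (cat == "punctuation" && txt == "*") "select_done"
        else unexpected()
      },
      select_list = {
        if (cat == "variable") { add_var(txt); "select_list" }
        else if (kw == "FROM") "from_iri"
        else if (kw == "WHERE") "after_where"
        else unexpected()
      },
      select_done = {
        if (kw == "FROM") "from_iri"
        else if (kw == "WHERE") "after_where"
        else unexpected()
      },
      from_iri = {
        if (cat == "iriref" && grepl(">$", txt)) {
          from_iris <- c(from_iris, substr(txt, 2, nchar(txt) - 1))
          "select_done"
        } else unexpected()
      },
      after_where = ,
      group_open = {
        if (cat == "punctuation" && txt == "{") { depth <- depth + 1L; "bgp_subject" }
        else unexpected()
      },
      bgp_subject = {
        if (cat %in% c("variable", "iriref", "prefixed_name")) {
          cur <- new_pattern(); cur$subject <- resolve(tok); "bgp_predicate"
        } else if (cat == "punctuation" && txt == "}") {
          depth <- depth - 1L
          if (depth == 0L) "done" else "bgp_subject"
        } else if (kw %in% c("OPTIONAL", "UNION")) "group_open"
        else if (kw == "FILTER") { filter_depth <- 0L; return_state <- "bgp_subject"; state }
        else unexpected()
      },
      bgp_predicate = {
        if (cat %in% c("variable", "iriref", "prefixed_name") ||
            (cat == "keyword" && txt == "a")) {
          cur$predicate <- resolve(tok); "bgp_object"
        } else unexpected()
      },
      bgp_object = {
        if (cat %in% c("variable", "iriref", "prefixed_name", "literal")) {
          cur$object <- resolve(tok); "bgp_after"
        } else unexpected()
      },
      bgp_after = {
        if (cat == "punctuation" && txt == ".") { close_triple(); "bgp_subject" }
        else if (cat == "punctuation" && txt == ";") {
          subj <- cur$subject; close_triple()
          cur <- new_pattern(); cur$subject <- subj
          "bgp_predicate"
        } else if (cat == "punctuation" && txt == ",") {
          subj <- cur$subject; pred <- cur$predicate; close_triple()
          cur <- new_pattern(); cur$subject <- subj; cur$predicate <- pred
          "bgp_object"
        } else if (cat == "punctuation" && txt == "}") {
          close_triple()
          depth <- depth - 1L
          if (depth == 0L) "done" else "bgp_subject"
        } else if (kw %in% c("OPTIONAL", "UNION")) { close_triple(); "group_open" }
        else if (kw == "FILTER") {
          close_triple(); filter_depth <- 0L; return_state <- "bgp_subject"; state
        } else unexpected()
      },
      done = unexpected(),
      unexpected()
    )
  }

  # the in-progress pattern is visible as the (possibly partial) last triple
  open_triples <- triples
  if (!is.null(cur) && cur$subject$kind != "missing") {
    open_triples[[length(open_triples) + 1L]] <- cur
  }

  info <- state_position(state, !is.na(filter_depth))
  list(position = info$position,
       expects = info$expects,
       expected_keywords = info$keywords,
       state = state,
       prefixes = prefixes,
       variables = variables,
       triples = open_triples,
       from_iris = from_iris)
}

# Position + completable categories for each parser state. States where only
# punctuation can follow map to the nearest enum value with an empty
# 'expects' set, so the suggestion engine emits nothing there.
state_position <- function(state, in_filter) {
  if (in_filter) {
    return(list(position = "KEYWORD", expects = character(), keywords = character()))
  }
  switch(state,
    start = list(position = "KEYWORD", expects = "keyword",
                 keywords = c("PREFIX", "SELECT")),
    prefix_name = list(position = "PREFIX_NAME", expects = "prefixed_name",
                       keywords = character()),
    prefix_iri = list(position = "PREFIX_IRI", expects = "iriref",
                      keywords = character()),
    select_head = list(position = "SELECT_VAR", expects = "variable",
                       keywords = "DISTINCT"),
    select_list = list(position = "SELECT_VAR",
                       expects = c("variable", "keyword"),
                       keywords = c("FROM", "WHERE")),
    select_done = list(position = "KEYWORD", expects = "keyword",
                       keywords = c("FROM", "WHERE")),
    from_iri = list(position = "FROM_IRI", expects = "iriref",
                    keywords = character()),
    after_where = ,
    group_open = list(position = "SUBJECT", expects = character(),
                      keywords = character()),
    bgp_subject = list(position = "SUBJECT",
                       expects = c("variable", "term"),
                       keywords = character()),
    bgp_predicate = list(position = "PREDICATE",
                         expects = c("variable", "term"),
                         keywords = "a"),
    bgp_object = list(position = "OBJECT",
                      expects = c("variable", "term", "literal"),
                      keywords = character()),
    bgp_after = list(position = "OBJECT", expects = character(),
                     keywords = character()),
    done = list(position = "KEYWORD", expects = character(),
                keywords = character()),
    list(position = "KEYWORD", expects = character(), keywords = character())
  )
}

#' Connected component of the query graph around a variable
#'
#' Triple patterns are linked when they share a variable; the neighborhood
#' of `var` is the transitive closure of that relation, together with the
#' named individuals (IRIs in subject or object slots) found inside it.
#'
#' @param context A `completion_context` from [parse_partial()].
#' @param var Variable name (with or without the leading `?`).
#' @return A list with `patterns` (list of triple patterns) and
#'   `individuals` (character vector of IRIs). A variable used in no triple
#'   yields empty sets.
#' @export
graph_neighborhood <- function(context, var) {
  var <- sub("^[?$]", "", var)
  triples <- context$triples
  pat_vars <- lapply(triples, function(p) {
    v <- list(p$subject, p$predicate, p$object)
    unique(vapply(v[vapply(v, function(x) x$kind == "variable", TRUE)],
                  function(x) x$value, ""))
  })
  reached_vars <- var
  in_comp <- rep(FALSE, length(triples))
  repeat {
    changed <- FALSE
    for (k in seq_along(triples)) {
      if (!in_comp[k] && length(intersect(pat_vars[[k]], reached_vars)) > 0) {
        in_comp[k] <- TRUE
        reached_vars <- union(reached_vars, pat_vars[[k]])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp <- triples[in_comp]
  inds <- character()
  for (p in comp) {
    for (slot in list(p$subject, p$object)) {
      if (slot$kind == "iri") inds <- union(inds, slot$value)
    }
  }
  list(patterns = comp, individuals = inds)
}
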