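# Shared fixture builders (cached per test run) and a tiny scripted-session
# driver used by the walkthrough tests.

.wt_cache <- new.env(parent = emptyenv())

wt_fixture <- function() {
  if (is.null(.wt_cache$fx)) {
    .wt_cache$fx <- walkthrough_fixture(file.path(tempdir(), "wt-fixture"))
  }
  .wt_cache$fx
}

wt_index <- function(german = FALSE, rdfxml = FALSE) {
  key <- paste0("ix_", german, "_", rdfxml)
  if (is.null(.wt_cache[[key]])) {
    .wt_cache[[key]] <- walkthrough_index(wt_fixture(), german = german,
                                          rdfxml = rdfxml)
  }
  .wt_cache[[key]]
}

wt_registry <- function() {
  if (is.null(.wt_cache$reg)) {
    .wt_cache$reg <- read_registry(wt_fixture()$registry_json)
  }
  .wt_cache$reg
}

# --- scripted composition session ------------------------------------------

session_new <- function(index, registry = NULL, lang = NULL) {
  list(text = "", index = index, registry = registry, lang = lang)
}

session_type <- function(st, txt) {
  st$text <- paste0(st$text, txt)
  st
}

session_suggest <- function(st) {
  suggest(st$text, nchar(st$text), st$index, st$registry, lang = st$lang)
}

# Accept the first suggestion satisfying `pick` (a predicate function or a
# display string); errors if none matches.
session_accept <- function(st, pick) {
  if (is.character(pick)) {
    want <- pick
    pick <- function(s) s$display == want
  }
  hits <- Filter(pick, session_suggest(st))
  if (length(hits) == 0) stop("no matching suggestion to accept")
  st$text <- apply_suggestion(st$text, nchar(st$text), hits[[1]])$text
  st
}

# Extract the triple-pattern skeleton of a complete query: one row per
# triple, nodes rendered as kind:value with variables renamed positionally,
# so two structurally identical queries compare equal.
query_skeleton <- function(text) {
  ctx <- parse_partial(text, nchar(text))
  seen <- character()
  node_key <- function(n) {
    if (n$kind == "variable") {
      if (!n$value %in% seen) seen <<- c(seen, n$value)
      paste0("var", match(n$value, seen))
    } else {
      paste0(n$kind, ":", n$value)
    }
  }
  vapply(ctx$triples, function(p) {
    paste(node_key(p$subject), node_key(p$predicate), node_key(p$object))
  }, "")
}
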