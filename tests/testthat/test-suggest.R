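# Suggestion engine: dispatch, ranking, URI substitution, FROM resolution.

test_that("keyword, namespace, variable, predicate and individual dispatch", {
  ix <- wt_index()
  s <- suggest("pr", 2, ix)
  expect_equal(s[[1]]$display, "PREFIX")
  expect_equal(s[[1]]$category, "keyword")

  s <- suggest("PREFIX path", 11, ix)
  expect_true(any(vapply(s, function(x) grepl("Kyoto", x$display), TRUE)))
  expect_true(all(vapply(s, function(x) x$category == "prefix", TRUE)))

  st <- "SELECT ?gene ?protein WHERE { ?g"
  s <- suggest(st, nchar(st), ix)
  expect_equal(s[[1]]$display, "?gene")
  expect_equal(s[[1]]$category, "variable")

  st <- "SELECT ?gene WHERE { ?gene <http://e/p> caff"
  s <- suggest(st, nchar(st), ix)
  expect_equal(s[[1]]$display, "human caffeine metabolism pathway")
  expect_equal(s[[1]]$category, "individual")

  st <- "SELECT ?gene WHERE { ?gene parti"
  s <- suggest(st, nchar(st), ix)
  expect_length(s, 2)
  expect_setequal(vapply(s, function(x) x$display, ""),
                  c("has participant", "is participant in"))
  expect_true(all(vapply(s, function(x) nzchar(x$description), TRUE)))
})

test_that("classes are offered after 'a', individuals otherwise", {
  ix <- wt_index()
  st <- "SELECT ?x WHERE { ?x a KEGG"
  s <- suggest(st, nchar(st), ix)
  expect_true(all(vapply(s, function(x) x$category == "class", TRUE)))
  expect_true("KEGG pathway record" %in% vapply(s, function(x) x$display, ""))

  st <- "SELECT ?x WHERE { ?x <http://e/p> KEGG"
  s <- suggest(st, nchar(st), ix)
  expect_false(any(vapply(s, function(x) x$category == "class", TRUE)))
})

test_that("accepted labels are rewritten to prefixed names or full IRIs", {
  ix <- wt_index()
  st <- "PREFIX SIO: <http://semanticscience.org/resource/> SELECT ?g WHERE { ?g parti"
  s <- suggest(st, nchar(st), ix)
  pick <- Filter(function(x) x$display == "is participant in", s)[[1]]
  expect_equal(pick$insertion, "SIO:SIO_000062")
  r <- apply_suggestion(st, nchar(st), pick)
  expect_match(r$text, "\\?g SIO:SIO_000062 $")
  expect_equal(r$cursor, nchar(r$text))

  # no covering prefix -> full IRI in angle brackets
  st2 <- "SELECT ?g WHERE { ?g <http://e/p> caff"
  s2 <- suggest(st2, nchar(st2), ix)[[1]]
  expect_equal(s2$insertion, "<http://lsrn.org/KEGG_PATHWAY:hsa00232>")

  # keyword splice at the very start
  r3 <- apply_suggestion("pr", 2, suggest("pr", 2, ix)[[1]])
  expect_equal(r3$text, "PREFIX ")
})

test_that("every emitted suggestion re-parses in the same grammatical position", {
  ix <- wt_index()
  reg <- wt_registry()
  category_tokens <- list(
    keyword = "keyword", variable = "variable",
    prefix = c("prefixed_name", "iriref"),
    property = c("prefixed_name", "iriref"),
    individual = c("prefixed_name", "iriref"),
    class = c("prefixed_name", "iriref"))
  queries <- c(
    "pr", "PREFIX pa", "PREFIX SIO: <htt",
    "PREFIX SIO: <http://semanticscience.org/resource/> SELECT ?gene ?protein WHERE { ?g",
    "SELECT ?gene WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> parti",
    "SELECT ?gene WHERE { ?gene <http://e/p> caff",
    "SELECT ?gene WHERE { ?gene a ")
  for (q in queries) {
    before <- parse_partial(q, nchar(q))
    for (s in suggest(q, nchar(q), ix, reg)) {
      expect_true(nzchar(s$insertion))
      r <- apply_suggestion(q, nchar(q), s)
      expect_no_error(parse_partial(r$text, r$cursor))
      completed <- tokenize_sparql(substr(r$text, 1, r$cursor - 1))
      lastcat <- completed$category[nrow(completed)]
      expect_true(lastcat %in% category_tokens[[s$category]])
      # the inserted token occupies the span that was being completed
      expect_equal(completed$start[nrow(completed)], before$current_span[1])
    }
  }
})

test_that("accepting the English and the German label yields byte-identical queries", {
  ixd <- wt_index(german = TRUE)
  base <- "PREFIX SIO: <http://semanticscience.org/resource/> SELECT ?gene WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> "
  en <- paste0(base, "parti")
  de <- paste0(base, "Bet")
  s_en <- Filter(function(x) x$display == "has participant",
                 suggest(en, nchar(en), ixd))[[1]]
  s_de <- Filter(function(x) x$display == "hat Beteiligten",
                 suggest(de, nchar(de), ixd))[[1]]
  expect_equal(s_en$target_uri, s_de$target_uri)
  expect_identical(apply_suggestion(en, nchar(en), s_en)$text,
                   apply_suggestion(de, nchar(de), s_de)$text)
})

test_that("typing more characters only narrows term suggestions", {
  ix <- wt_index()
  base <- "SELECT ?gene WHERE { ?gene "
  for (pair in list(c("par", "parti"), c("co", "code"), c("i", "is"))) {
    short <- suggest(paste0(base, pair[1]), index = ix, max_suggestions = 100)
    long <- suggest(paste0(base, pair[2]), index = ix, max_suggestions = 100)
    expect_true(all(vapply(long, function(x) x$target_uri, "") %in%
                      vapply(short, function(x) x$target_uri, "")))
  }
})

test_that("suggestion lists are deterministic and capped", {
  ix <- wt_index()
  q <- "SELECT ?x WHERE { ?x <http://e/p> "
  a <- suggest(q, nchar(q), ix)
  b <- suggest(q, nchar(q), ix)
  expect_identical(a, b)
  expect_lte(length(suggest(q, nchar(q), ix, max_suggestions = 3)), 3)
})

test_that("no suggestions are emitted where only punctuation can follow", {
  ix <- wt_index()
  expect_length(suggest("SELECT ?x WHERE ", index = ix), 0)
  expect_length(suggest("SELECT ?x WHERE { ?a <http://e/p> ?b ", index = ix), 0)
})

test_that("FROM clauses are fetched, indexed once, and failures are non-fatal", {
  fx <- wt_fixture()
  ix <- wt_index()
  q <- paste0("SELECT ?x FROM <", fx$props_de_ttl, "> WHERE { ")
  ctx <- parse_partial(q, nchar(q))
  ix2 <- resolve_from_clauses(ctx, ix)
  expect_equal(nrow(match_terms("Bet", ix2, kind = "property", lang = "de")), 1)
  # second resolution is a no-op (already loaded)
  ix3 <- resolve_from_clauses(ctx, ix2)
  expect_identical(ix3, ix2)

  # no FROM clause: unchanged
  ctx0 <- parse_partial("SELECT ?x WHERE { ", 18)
  expect_identical(resolve_from_clauses(ctx0, ix), structure(ix, from_loaded = character()))

  # unreachable IRI: warning, index unchanged apart from bookkeeping
  qbad <- "SELECT ?x FROM <http://nowhere.invalid/onto.owl> WHERE { "
  ctxb <- parse_partial(qbad, nchar(qbad))
  expect_warning(ixb <- resolve_from_clauses(ctxb, ix), "skipped")
  expect_equal(n_terms(ixb), n_terms(ix))
})

test_that("suggestion JSON follows the shared schema", {
  ix <- wt_index()
  s <- suggest("pr", 2, ix)
  parsed <- jsonlite::fromJSON(suggestions_to_json(s), simplifyVector = FALSE)
  expect_length(parsed, length(s))
  expect_setequal(names(parsed[[1]]),
                  c("display", "description", "insertion", "uri", "category",
                    "highlighted"))
  expect_identical(parsed[[1]]$display, "PREFIX")
  expect_false(parsed[[1]]$highlighted)
})
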