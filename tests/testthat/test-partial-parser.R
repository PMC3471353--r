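# Tokenizer and partial parser.

test_that("tokenizer classifies the SPARQL lexical categories", {
  tok <- tokenize_sparql("SELECT ?gene")
  expect_equal(tok$category, c("keyword", "variable"))
  expect_equal(tok$text, c("SELECT", "?gene"))

  tok <- tokenize_sparql("PREFIX sio: <http://semanticscience.org/resource/>")
  expect_equal(tok$category, c("keyword", "prefixed_name", "iriref"))

  expect_equal(nrow(tokenize_sparql("")), 0)

  tok <- tokenize_sparql('?g sio:p "label"@en .')
  expect_equal(tok$category,
               c("variable", "prefixed_name", "literal", "punctuation"))
})

test_that("token spans tile the input and reproduce it with its whitespace", {
  texts <- c("SELECT ?x  WHERE\n{ ?x a <http://e/C> . }",
             "pr", "PREFIX s: <http://x/> SELECT * WHERE { ?a s:p \"v\" }",
             "?s <http://e/p> ?o ; <http://e/q> ?z")
  for (text in texts) {
    tok <- tokenize_sparql(text)
    expect_true(all(diff(tok$start) > 0))
    expect_true(all(tok$end > tok$start))
    expect_true(all(tok$start[-1] >= tok$end[-nrow(tok)]))  # non-overlapping
    for (k in seq_len(nrow(tok))) {
      expect_equal(substr(text, tok$start[k] + 1, tok$end[k]), tok$text[k])
    }
    # gaps between tokens are pure whitespace
    gaps <- c(mapply(function(a, b) substr(text, a + 1, b),
                     c(0, tok$end), c(tok$start, nchar(text))))
    expect_true(all(grepl("^\\s*$", gaps)))
  }
})

test_that("unknown runs never raise and keywords are case-insensitive", {
  tok <- tokenize_sparql("select @@ ?x éé")
  expect_equal(tok$category[1], "keyword")
  expect_true("unknown" %in% tok$category)
  expect_equal(nrow(tokenize_sparql("üö")), 1)
})

test_that("position and context are recovered at the cursor", {
  ctx <- parse_partial("pr", 2)
  expect_equal(ctx$position, "KEYWORD")
  expect_equal(ctx$current_token, "pr")
  expect_length(ctx$prefixes, 0)
  expect_length(ctx$variables, 0)

  ctx <- parse_partial("SELECT ?gene ?protein WHERE { ?g")
  expect_equal(ctx$position, "SUBJECT")
  expect_equal(ctx$current_token, "?g")
  expect_equal(ctx$variables, c("gene", "protein"))

  ctx <- parse_partial("", 0)
  expect_equal(ctx$position, "KEYWORD")
  expect_equal(ctx$current_token, "")
})

test_that("'.', ';' and ',' close, repeat-subject and repeat-predicate", {
  q <- "SELECT * WHERE { ?a <http://e/p> ?b ; <http://e/q> ?c , ?d . ?e "
  ctx <- parse_partial(q)
  expect_equal(ctx$position, "PREDICATE")
  tr <- ctx$triples
  expect_length(tr, 4)  # three closed + the partial one
  expect_equal(tr[[2]]$subject$value, "a")
  expect_equal(tr[[2]]$predicate$value, "http://e/q")
  expect_equal(tr[[3]]$subject$value, "a")
  expect_equal(tr[[3]]$predicate$value, "http://e/q")
  expect_equal(tr[[3]]$object$value, "d")
  expect_equal(tr[[4]]$subject$value, "e")
  expect_equal(tr[[4]]$predicate$kind, "missing")
})

test_that("'a' expands to rdf:type and prefixed names expand through PREFIX", {
  q <- "PREFIX ex: <http://e/> SELECT * WHERE { ?x a ex:C "
  ctx <- parse_partial(q)
  tr <- ctx$triples[[1]]
  expect_equal(tr$predicate$value,
               "http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
  expect_equal(tr$object$value, "http://e/C")
})

test_that("whitespace runs between tokens never change the context", {
  base <- "PREFIX ex: <http://e/> SELECT ?x WHERE { ?x ex:p "
  spaced <- gsub(" ", "\n  \t", base)
  a <- parse_partial(base)
  b <- parse_partial(spaced)
  for (field in c("position", "prefixes", "variables", "triples", "from_iris")) {
    expect_identical(a[[field]], b[[field]])
  }
})

test_that("text after the cursor never changes the reported context", {
  full <- "SELECT ?gene ?protein WHERE { ?g"
  for (cut in c(2, 9, 14, 25, 31)) {
    a <- parse_partial(substr(full, 1, cut), cut)
    b <- parse_partial(full, cut)
    for (field in c("position", "current_token", "prefixes", "variables",
                    "triples")) {
      expect_identical(a[[field]], b[[field]])
    }
  }
})

test_that("grammar violations carry the offset of the offending token", {
  err <- tryCatch(parse_partial("WHERE ?x ", 9), sparql_parse_error = identity)
  expect_s3_class(err, "sparql_parse_error")
  expect_equal(err$offset, 0)

  err <- tryCatch(parse_partial("SELECT ?x WHERE { ?a <http://e/p> ?b ?c ", 40),
                  sparql_parse_error = identity)
  expect_equal(err$offset, 37)

  # undeclared prefix inside a triple pattern
  expect_error(parse_partial("SELECT * WHERE { ?x ex:p ", 25),
               class = "sparql_parse_error")
})

test_that("graph neighborhoods follow shared-variable connectivity", {
  q <- paste0("SELECT * WHERE { <http://e/i1> <http://e/p1> ?gene . ",
              "?gene <http://e/p2> ?protein . ",
              "?other <http://e/p3> <http://e/i2> }")
  ctx <- parse_partial(q, nchar(q))
  nb <- graph_neighborhood(ctx, "protein")
  expect_length(nb$patterns, 2)
  expect_equal(nb$individuals, "http://e/i1")
  # disconnected component stays out
  nb2 <- graph_neighborhood(ctx, "other")
  expect_length(nb2$patterns, 1)
  expect_equal(nb2$individuals, "http://e/i2")
  # absent variable
  expect_length(graph_neighborhood(ctx, "nope")$patterns, 0)
})

test_that("graph_neighborhood agrees with a union-find oracle on random queries", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    vars <- paste0("v", 1:4)
    mk_node <- function() {
      if (runif(1) < 0.6) list(kind = "variable", value = sample(vars, 1))
      else list(kind = "iri", value = paste0("http://e/i", sample(3, 1)))
    }
    triples <- lapply(seq_len(n), function(k) {
      list(subject = mk_node(),
           predicate = list(kind = "iri", value = "http://e/p"),
           object = mk_node())
    })
    ctx <- list(triples = triples)
    for (v in vars) {
      got <- graph_neighborhood(ctx, v)$patterns
      want <- triples[oracle_neighborhood(triples, v)]
      expect_setequal(
        vapply(got, function(p) paste(p$subject$value, p$object$value), ""),
        vapply(want, function(p) paste(p$subject$value, p$object$value), ""))
    }
  }
})
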