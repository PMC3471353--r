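# SADI-style registry: matchmaking, highlighting, filtering, propagation.

test_that("available_properties matches input classes exactly", {
  reg <- sadi_registry(data.frame(
    id = "s1", input_class = "http://e/Pathway",
    property = "http://e/hasParticipant", output_class = "http://e/Gene",
    stringsAsFactors = FALSE))
  expect_equal(available_properties("http://e/Pathway", reg),
               "http://e/hasParticipant")
  expect_length(available_properties("http://e/Other", reg), 0)
  expect_length(available_properties("http://e/Pathway", sadi_registry()), 0)
  # no subsumption: a subclass IRI does not match
  expect_length(available_properties("http://e/Pathway2", reg), 0)
})

test_that("registry JSON loads and validates", {
  reg <- wt_registry()
  expect_equal(nrow(reg$records), 2)
  expect_error(sadi_registry(data.frame(id = "x", input_class = "",
                                        property = "p", output_class = "",
                                        stringsAsFactors = FALSE)),
               "non-empty")
  expect_error(read_registry('{"nope": []}'), "services")
})

test_that("the walkthrough subject makes 'has participant' serviceable and highlighted", {
  ix <- wt_index()
  reg <- wt_registry()
  st <- "SELECT ?gene WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> parti"
  s <- suggest(st, nchar(st), ix, reg)
  hl <- vapply(s, function(x) x$highlighted, TRUE)
  disp <- vapply(s, function(x) x$display, "")
  expect_equal(disp[hl], "has participant")
  expect_equal(sum(hl), 1)
  expect_equal(s[[1]]$display, "has participant")  # highlighted ranks first
})

test_that("suggest with no registry equals suggest with an empty registry", {
  ix <- wt_index()
  queries <- c("SELECT ?gene WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> parti",
               "SELECT ?gene WHERE { ?gene ",
               "pr")
  for (q in queries) {
    expect_identical(suggest(q, nchar(q), ix, NULL),
                     suggest(q, nchar(q), ix, sadi_registry()))
  }
})

test_that("an unknown-typed subject vetoes nothing", {
  ix <- wt_index()
  reg <- wt_registry()
  st <- "SELECT ?x WHERE { ?x parti"  # ?x has no propagated type
  with_reg <- suggest(st, nchar(st), ix, reg)
  without <- suggest(st, nchar(st), ix, NULL)
  expect_identical(with_reg, without)
  expect_false(any(vapply(with_reg, function(x) x$highlighted, TRUE)))
})

test_that("registry-only properties are filtered unless serviceable", {
  ix <- wt_index()
  reg <- sadi_registry(data.frame(
    id = c("s1", "s2"),
    input_class = c("http://example.org/lsrn/KEGG_PATHWAY_Record",
                    "http://e/Unrelated"),
    property = c("http://e/registryOnlyGood", "http://e/registryOnlyBad"),
    output_class = c("", ""),
    stringsAsFactors = FALSE))
  st <- "SELECT ?g WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> registryOnly"
  s <- suggest(st, nchar(st), ix, reg)
  uris <- vapply(s, function(x) x$target_uri, "")
  expect_true("http://e/registryOnlyGood" %in% uris)
  expect_false("http://e/registryOnlyBad" %in% uris)
  expect_true(s[[which(uris == "http://e/registryOnlyGood")]]$highlighted)

  # ontology-known properties are never filtered, only left unhighlighted
  st2 <- "SELECT ?g WHERE { <http://lsrn.org/KEGG_PATHWAY:hsa00232> parti"
  s2 <- suggest(st2, nchar(st2), ix, reg)
  expect_length(s2, 2)
  expect_false(any(vapply(s2, function(x) x$highlighted, TRUE)))
})

test_that("service output types flow across clauses", {
  ix <- wt_index()
  reg <- wt_registry()
  q <- paste0("PREFIX SIO: <http://semanticscience.org/resource/> ",
              "SELECT ?gene ?protein WHERE { ",
              "<http://lsrn.org/KEGG_PATHWAY:hsa00232> SIO:SIO_000132 ?gene . ",
              "?gene ")
  ctx <- parse_partial(q, nchar(q))
  assignment <- propagate_types(ctx, reg, individual_types(ix))
  expect_equal(assignment$gene, "http://example.org/lsrn/KEGG_GENE_Record")
  # which makes codes-for serviceable (and highlighted) in clause 2
  ixd <- index_ontology(wt_fixture()$props_de_ttl, ix)
  s <- suggest(paste0(q, "codi"), index = ixd, registry = reg)
  expect_equal(s[[1]]$display, "codiert für")
  expect_true(s[[1]]$highlighted)
})

test_that("no named individuals means an empty assignment", {
  reg <- wt_registry()
  ctx <- parse_partial("SELECT ?a ?b WHERE { ?a <http://e/p> ?b ", 40)
  expect_length(propagate_types(ctx, reg, individual_types(wt_index())), 0)
})

test_that("the propagation fixpoint matches the brute-force closure", {
  for (seed in 1:40) {
    case <- random_propagation_case(seed)
    ctx <- list(triples = case$triples)
    got <- propagate_types(ctx, sadi_registry(case$records), case$ind_types)
    want <- oracle_closure(case$triples, case$records, case$ind_types)
    expect_setequal(as.character(names(got)), as.character(names(want)))
    for (v in names(want)) expect_setequal(got[[v]], unique(want[[v]]))
  }
})

test_that("propagation is monotone in records and triples", {
  checked <- 0L
  for (seed in 101:120) {
    case <- random_propagation_case(seed)
    if (nrow(case$records) < 2 || length(case$triples) < 2) next
    ctx <- list(triples = case$triples)
    reg_all <- sadi_registry(case$records)
    base <- propagate_types(ctx, reg_all, case$ind_types)
    fewer <- sadi_registry(case$records[-1, , drop = FALSE])
    sub <- propagate_types(ctx, fewer, case$ind_types)
    for (v in names(sub)) expect_true(all(sub[[v]] %in% base[[v]]))
    sub2 <- propagate_types(list(triples = case$triples[-1]), reg_all,
                            case$ind_types)
    for (v in names(sub2)) expect_true(all(sub2[[v]] %in% base[[v]]))
    checked <- checked + 1L
  }
  expect_gt(checked, 5)
})
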