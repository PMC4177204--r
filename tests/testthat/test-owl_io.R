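test_that("a bare class serializes to exactly its type, label and subclass triples", {
  kb <- kb_new()
  P <- term_id("T", 1); A <- term_id("T", 2)
  kb_register_class(kb, ontology_class(P, "parent"))
  kb_register_class(kb, ontology_class(A, "child", parents = P))
  v <- to_triples(kb)
  class_triples <- Filter(function(t) t$s$value == paste0("obo:", A), v$triples)
  expect_length(class_triples, 3L)
  preds <- sort(vapply(class_triples, function(t) t$p$value, character(1)))
  expect_equal(preds, c("rdf:type", "rdfs:label", "rdfs:subClassOf"))
})

test_that("the three-age-group leaf contains a unionOf list with 3 members", {
  kb <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  v <- to_triples(kb)
  unions <- Filter(function(t) t$p$value == "owl:unionOf", v$triples)
  expect_length(unions, 1L)
  # walk the RDF list
  by_subj <- list()
  for (t in v$triples)
    if (t$s$kind == "blank")
      by_subj[[t$s$value]] <- c(by_subj[[t$s$value]], list(t))
  n <- 0L; cur <- unions[[1]]$o
  while (!(cur$kind == "iri" && cur$value == "rdf:nil")) {
    ts <- by_subj[[cur$value]]
    n <- n + 1L
    cur <- Filter(function(t) t$p$value == "rdf:rest", ts)[[1]]$o
  }
  expect_equal(n, 3L)
})

test_that("triple counts equal the per-construct tally oracle", {
  kb <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  expect_equal(length(to_triples(kb)$triples), oracle_triple_count(kb))
  withr::with_seed(8, {
    g <- generate(small_gen(8))
    kb2 <- compile_kb(g$records, g$seed_terms)
    expect_equal(length(to_triples(kb2)$triples), oracle_triple_count(kb2))
  })
})

test_that("turtle round-trips are isomorphic and writes are canonical", {
  kb <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  v <- to_triples(kb)
  f1 <- withr::local_tempfile(fileext = ".ttl")
  f2 <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(v, f1)
  back <- read_turtle(f1)
  expect_true(triples_isomorphic(v, back))
  write_turtle(back, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a hand-minimized turtle file parses to its three triples", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix ex: <http://example.org/> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "<http://example.org/a> rdfs:label \"thing a\" ;",
    "    rdfs:subClassOf <http://example.org/b> , <http://example.org/c> ."
  ), f)
  v <- read_turtle(f)
  expect_length(v$triples, 3L)
  expect_error(read_turtle({
    bad <- withr::local_tempfile(fileext = ".ttl")
    writeLines("<http://example.org/a> rdfs:label", bad)
    bad
  }), class = "vaekb_parse")
})

test_that("a KB rebuilt from its triples preserves classes, axioms and associations", {
  kb <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  f <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(to_triples(kb), f)
  kb2 <- kb_from_triples(read_turtle(f))
  expect_setequal(names(kb2$classes), names(kb$classes))
  expect_equal(count_vae_per_vaccine(kb2), count_vae_per_vaccine(kb))
  expect_equal(max_occurrence(kb2), max_occurrence(kb))
  expect_true(triples_isomorphic(to_triples(kb2), to_triples(kb)))
})
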