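test_that("normalization splits conjunctions and encapsulates datatype parts", {
  kb <- kb_new()
  A <- term_id("T", 1); B <- term_id("T", 2); C <- term_id("T", 3)
  kb_register_class(kb, ontology_class(B, "B"))
  kb_register_class(kb, ontology_class(C, "C"))
  kb_register_class(kb, ontology_class(
    A, "A", expression = ce_and(ce_named(B),
                                ce_some(PROP_OCCURS_IN, ce_named(C)))))
  n <- el_normalize(kb)
  types <- vapply(n$axioms, function(a) a$type, character(1))
  expect_setequal(unique(types), c("sub", "ex_rhs"))
  expect_true(any(vapply(n$axioms, function(a)
    a$type == "sub" && a$lhs == A && a$rhs == B, logical(1))))
  expect_true(any(vapply(n$axioms, function(a)
    a$type == "ex_rhs" && a$lhs == A && a$filler == C, logical(1))))

  # purely atomic KB: normalization emits only the asserted subs
  ch <- chain_kb()
  n2 <- el_normalize(ch$kb)
  expect_length(n2$axioms, 2L)
  expect_length(n2$aux_map, 0L)

  # pattern-style axiom: datatype/disjunction parts become opaque atoms
  akb <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  n3 <- el_normalize(akb)
  expect_true(any(grepl("^opq:", names(n3$aux_map))))
  opq <- unlist(n3$aux_map[grepl("^opq:", names(n3$aux_map))])
  expect_true(all(grepl("^(or|interval|value)\\(", opq)))
})

test_that("disjunction outside an 'occurs in population' filler is rejected", {
  kb <- kb_new()
  A <- term_id("T", 1); B <- term_id("T", 2); C <- term_id("T", 3)
  kb_register_class(kb, ontology_class(B, "B"))
  kb_register_class(kb, ontology_class(C, "C"))
  kb_register_class(kb, ontology_class(
    A, "A", expression = ce_or(ce_named(B), ce_named(C))))
  expect_error(el_normalize(kb), class = "vaekb_unsupported_axiom")
})

test_that("classification derives the injection-site subsumptions of the figure hierarchy", {
  kb <- load_fixture("figure4")
  classify_kb(kb)
  isae <- kb_class(kb, "injection-site adverse event")$id
  pain <- kb_class(kb, "injection-site pain AE")$id
  expect_true(isae %in% kb$inferred[[pain]])
  # inferred strictly extends asserted for the defined parent
  asserted <- kb_descendants(kb, isae, inferred = FALSE)
  inferred <- kb_descendants(kb, isae, inferred = TRUE)
  expect_true(all(asserted %in% inferred))
  expect_gt(length(inferred), length(asserted))

  edges <- inferred_only_edges(kb)
  under_isae <- edges[edges$parent == isae, ]
  expect_equal(under_isae$child_label,
               c("injection-site pain AE", "injection-site redness AE"))
})

test_that("purely asserted KBs infer exactly the transitive closure", {
  ch <- chain_kb()
  classify_kb(ch$kb)
  expect_setequal(ch$kb$inferred[[ch$A]], c(ch$B, ch$C))
  expect_equal(nrow(inferred_only_edges(ch$kb)), 0L)
  expect_error(inferred_only_edges(chain_kb()$kb),
               class = "vaekb_classification_not_run")
})

test_that("classification is idempotent and monotone", {
  withr::with_seed(99, {
    kb <- random_el_kb(n = 20L)
    classify_kb(kb)
    first <- kb$inferred
    classify_kb(kb)
    expect_identical(kb$inferred, first)

    # add an axiom: no subsumption disappears
    ids <- names(kb$classes)
    kb_add_parent(kb, ids[length(ids)], ids[1L])
    classify_kb(kb)
    for (id in ids)
      expect_true(all(first[[id]] %in% kb$inferred[[id]]))
  })
})

test_that("classification agrees with the brute-force saturation oracle", {
  withr::with_seed(4242, {
    for (rep in 1:25) {
      kb <- random_el_kb(n = sample(5:30, 1L))
      classify_kb(kb)
      expect_identical(kb$inferred, oracle_classify(kb))
    }
  })
})

test_that("inferred-only edges equal the oracle set difference on random KBs", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      kb <- random_el_kb(n = 15L)
      classify_kb(kb)
      edges <- inferred_only_edges(kb)
      oracle <- oracle_classify(kb)
      for (i in seq_len(nrow(edges))) {
        expect_true(edges$parent[i] %in% oracle[[edges$child[i]]])
        expect_false(edges$parent[i] %in%
                       vaekb:::kb_ancestors(kb, edges$child[i]))
      }
    }
  })
})
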