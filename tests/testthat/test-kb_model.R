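test_that("term ids render, parse and validate", {
  expect_equal(term_id("OVAE", 1), "OVAE_0000001")
  expect_equal(term_id("OAE", 369), "OAE_0000369")
  expect_true(all(is_term_id(c("OVAE_0000001", "VO_0010737"))))
  expect_false(any(is_term_id(c("OVAE_1", "ovae 1", "OVAE_00000001"))))
  expect_equal(term_prefix("UBERON_0012100"), "UBERON")
  expect_error(term_id("OVAE", 10000000), class = "vaekb_range")
})

test_that("class registration enforces labels, references and acyclicity", {
  kb <- kb_new()
  parent <- term_id("OAE", 4)
  kb_register_class(kb, ontology_class(parent, "behavior and neurological AE"))
  pain <- term_id("OAE", 3)
  kb_register_class(kb, ontology_class(pain, "pain AE", parents = parent))
  expect_equal(kb_class(kb, pain)$label, "pain AE")
  expect_equal(kb_class(kb, "pain AE")$id, pain)
  expect_length(kb_class(kb, pain)$parents, 1L)

  expect_error(kb_register_class(kb, ontology_class(term_id("OAE", 99), "pain AE")),
               class = "vaekb_duplicate_term")
  expect_error(kb_register_class(kb, ontology_class(pain, "other")),
               class = "vaekb_duplicate_term")
  expect_error(
    kb_register_class(kb, ontology_class(term_id("OAE", 5), "orphan",
                                         parents = term_id("OAE", 77))),
    class = "vaekb_dangling_reference")
  # A under B then B under A
  expect_error(kb_add_parent(kb, parent, pain), class = "vaekb_cycle")
  expect_error(kb_add_parent(kb, pain, pain), class = "vaekb_cycle")
})

test_that("descendants follow asserted closure and match the DFS oracle", {
  ch <- chain_kb()
  expect_setequal(kb_descendants(ch$kb, ch$C), c(ch$A, ch$B))
  expect_equal(kb_descendants(ch$kb, ch$A), character())
  expect_error(kb_descendants(ch$kb, term_id("T", 9)),
               class = "vaekb_dangling_reference")
  expect_error(kb_descendants(ch$kb, ch$C, inferred = TRUE),
               class = "vaekb_classification_not_run")

  withr::with_seed(11, {
    for (rep in 1:5) {
      kb <- random_el_kb(n = 15L, p_def = 0)
      for (id in names(kb$classes))
        expect_equal(kb_descendants(kb, id), oracle_descendants(kb, id))
    }
  })
})

test_that("term statistics: totals are column sums; empty KB has only pattern properties", {
  s <- term_statistics(kb_new())
  tot <- s[s$source == "Total", ]
  expect_equal(tot$n_classes, 0L)
  expect_equal(tot$n_object_properties, 3L)
  expect_equal(tot$n_datatype_properties, 2L)
  body <- s[s$source != "Total", ]
  expect_equal(body$source[body$n_object_properties == 3], "OVAE")

  withr::with_seed(7, {
    kb <- random_el_kb(n = 25L)
    s <- term_statistics(kb)
    body <- s[s$source != "Total", ]
    tot <- s[s$source == "Total", ]
    expect_equal(tot$n_classes, sum(body$n_classes))
    expect_equal(tot$total, sum(body$total))
    # recount by brute-force iteration
    expect_equal(tot$n_classes, length(kb$classes))
    expect_equal(tot$n_object_properties,
                 sum(vapply(kb$properties, function(p) p$kind == "object",
                            logical(1))))
  })
})

test_that("descendants(asserted) is a subset of descendants(inferred) after classification", {
  withr::with_seed(23, {
    kb <- random_el_kb(n = 18L)
    classify_kb(kb)
    for (id in names(kb$classes)) {
      a <- kb_descendants(kb, id, inferred = FALSE)
      i <- kb_descendants(kb, id, inferred = TRUE)
      expect_true(all(a %in% i))
    }
  })
})
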