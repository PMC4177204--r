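test_that("id minting is auto-incremental and skips reserved ids", {
  m <- id_minter()
  expect_equal(mint_ovae_id(m), "OVAE_0000001")
  expect_equal(mint_ovae_id(m), "OVAE_0000002")
  expect_equal(mint_ovae_id(m), "OVAE_0000003")

  m2 <- id_minter(reserved = "OVAE_0000002")
  expect_equal(mint_ovae_id(m2), "OVAE_0000001")
  expect_equal(mint_ovae_id(m2), "OVAE_0000003")

  m3 <- id_minter(start = 9999999L)
  mint_ovae_id(m3)
  expect_error(mint_ovae_id(m3), class = "vaekb_capacity")
})

test_that("vaccine AE parent class follows the naming convention and is idempotent", {
  kb <- kb_new()
  register_seed <- vaekb_seed_terms()
  vaekb:::register_seed_terms(kb, register_seed)
  m <- id_minter(reserved = vapply(vaekb:::pattern_properties(),
                                   function(p) p$id, character(1)))
  vid <- term_id("VO", 10737)
  kb_register_class(kb, ontology_class(vid, "Recombivax HB",
                                       parents = kb_class(kb, "vaccine")$id))
  p1 <- vaccine_ae_parent(kb, vid, m)
  expect_equal(kb_class(kb, p1)$label, "Recombivax HB vaccine adverse event")
  expect_equal(vaccine_ae_parent(kb, vid, m), p1)
  # asserted under the 'vaccine adverse event' root, itself under 'adverse event'
  root <- kb_class(kb, "vaccine adverse event")
  expect_equal(kb_class(kb, p1)$parents, root$id)
  expect_equal(root$parents, kb_class(kb, "adverse event")$id)
})

test_that("leaf classes carry the pattern axiom with an OR-clause over age groups", {
  recs <- load_fixture("afluria")
  kb <- compile_kb(recs, vaekb_seed_terms())
  leaf <- kb_class(kb, "Afluria-associated injection-site pain AE")
  expect_false(is.null(leaf))
  expect_setequal(
    vapply(leaf$parents, function(p) kb$classes[[p]]$label, character(1)),
    c("injection-site pain AE", "Afluria vaccine adverse event"))
  e <- leaf$expression
  expect_equal(e$type, "and")
  pop <- Filter(function(a) identical(a$property, vaekb:::PROP_OCCURS_IN_POPULATION),
                e$args)[[1]]
  disj <- Filter(function(a) a$type == "or", pop$filler$args)
  expect_length(disj, 1L)
  expect_length(disj[[1]]$args, 3L)
  expect_equal(leaf$definition_source, recs$reference[1])

  # single age group: no disjunction node anywhere in the expression
  single <- kb_class(kb, "Afluria-associated headache AE")$expression
  expect_false(grepl("or(", vaekb:::ce_render(single), fixed = TRUE))
})

test_that("compilation is deterministic and conserves the association count", {
  recs <- load_fixture("afluria")
  seed <- vaekb_seed_terms()
  kb1 <- compile_kb(recs, seed)
  kb2 <- compile_kb(recs[rev(seq_len(nrow(recs))), ], seed)
  f1 <- withr::local_tempfile(fileext = ".ttl")
  f2 <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(to_triples(kb1), f1)
  write_turtle(to_triples(kb2), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # leaf count = distinct (vaccine, ae) pairs; labels follow the conventions
  expect_length(kb1$associations,
                length(unique(paste(recs$vaccine_vo_id, recs$oae_id))))
  for (a in kb1$associations) {
    leaf <- kb1$classes[[a$leaf]]
    expect_match(leaf$label, "associated")
    expect_match(leaf$label, " AE$")
    for (p in leaf$parents[grepl("^OVAE_", leaf$parents)])
      expect_match(kb1$classes[[p]]$label, "adverse event")
  }

  # compiling twice from identical inputs reproduces identical minted ids
  expect_identical(names(kb1$classes), names(compile_kb(recs, seed)$classes))
})

test_that("empty record list compiles to seed terms plus pattern infrastructure", {
  seed <- vaekb_seed_terms()
  kb <- compile_kb(data.frame(), seed)
  expect_length(kb$associations, 0L)
  expect_true(!is.null(kb_class(kb, "vaccine adverse event")))
  expect_true(!is.null(kb_class(kb, "human vaccinee population")))
  expect_equal(sum(!grepl("^OVAE_", names(kb$classes))), nrow(seed))
})

test_that("building a leaf twice returns the existing class", {
  recs <- load_fixture("afluria")
  kb <- compile_kb(recs, vaekb_seed_terms())
  m <- id_minter(reserved = names(kb$classes)[grepl("^OVAE_", names(kb$classes))])
  a <- kb$associations[[1]]
  expect_equal(build_vae_class(kb, a, m), a$leaf)
})
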