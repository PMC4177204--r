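test_that("per-vaccine counting: printed top-10 table reproduced, modes agree", {
  recs <- load_fixture("table2")
  counts <- attr(recs, "counts")
  kb <- compile_kb(recs, vaekb_seed_terms())
  tab <- count_vae_per_vaccine(kb)
  expect_equal(tab$label[1], "Recombivax HB vaccine adverse event")
  expect_equal(tab$n_vae[1], 20L)
  expect_equal(sort(tab$n_vae, decreasing = TRUE), sort(counts$n_vae,
                                                        decreasing = TRUE))
  lab <- count_vae_per_vaccine(kb, "label-convention")
  expect_equal(tab, lab)

  empty <- compile_kb(data.frame(), vaekb_seed_terms())
  expect_equal(nrow(count_vae_per_vaccine(empty)), 0L)
})

test_that("AE frequency percents follow count/total with half-up rounding", {
  kb <- compile_kb(load_fixture("table3"), vaekb_seed_terms())
  freq <- ae_frequency(kb)
  get <- function(ae) freq[freq$ae == ae, ]
  expect_equal(get("OAE_0000369")[, c("n_vaccines", "percent")],
               data.frame(n_vaccines = 43L, percent = 68.3),
               ignore_attr = TRUE)
  expect_equal(get("OAE_0000361")$percent, 54.0)
  expect_equal(get("OAE_0000390")$percent, 33.3)
  expect_equal(get("OAE_0000375")$percent, 30.2)

  one <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  f1 <- ae_frequency(one)
  expect_true(all(f1$n_vaccines == 1L))
  expect_true(all(f1$percent == 100.0))

  expect_error(ae_frequency(compile_kb(data.frame(), vaekb_seed_terms())),
               class = "vaekb_empty_kb")
})

test_that("age-stratified occurrence summary counts, means, and the child>adult flag", {
  # single association, single adult group at 97.5%
  recs <- load_fixture("typhim_vi")[1L, , drop = FALSE]
  kb <- compile_kb(recs, vaekb_seed_terms())
  tab <- occurrence_by_age(kb)
  adult <- tab[tab$group == "adult", ]
  expect_equal(adult$n, 1L)
  expect_equal(adult$mean_occurrence, 0.975)
  expect_equal(tab$n[tab$group == "child"], 0L)

  # only child-adult groups: child and adult rows count 0
  ca <- load_fixture("typhim_vi")[4L, , drop = FALSE]
  kb2 <- compile_kb(ca, vaekb_seed_terms())
  t2 <- occurrence_by_age(kb2)
  expect_equal(t2$n[t2$group %in% c("child", "adult")], c(0L, 0L))
  expect_equal(t2$n[t2$group == "child-adult"], 1L)

  # senior entries fold into adult; interval mode keeps them apart
  akb <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  t3 <- occurrence_by_age(akb)
  expect_equal(sum(t3$n), 11L)
  ti <- occurrence_by_age(akb, group_by = "interval")
  expect_true("65-Inf" %in% ti$group)
  expect_equal(sum(ti$n), 11L)
})

test_that("planted child-over-adult occurrence shift is flagged", {
  g <- generate(small_gen(5, n_vaccines = 12L, ae_vocabulary = 20L,
                          aes_per_vaccine = c(3L, 8L)))
  kb <- compile_kb(g$records, g$seed_terms)
  tab <- occurrence_by_age(kb)
  expect_true(attr(tab, "child_gt_adult"))
})

test_that("max occurrence returns the Typhim Vi entry and matches a linear scan", {
  kb <- compile_kb(load_fixture("typhim_vi"), vaekb_seed_terms())
  m <- max_occurrence(kb)
  expect_equal(m$vaccine_label, "Typhim Vi")
  expect_equal(m$ae_label, "injection-site tenderness AE")
  expect_equal(m$occurrence, 0.975)
  expect_equal(c(m$min, m$max), c(18, 40))

  # tie-break: all equal -> alphabetically first (vaccine, AE) pair
  recs <- load_fixture("afluria")
  recs$vae_occurrence <- "10%"
  tie <- compile_kb(recs, vaekb_seed_terms())
  mt <- max_occurrence(tie)
  expect_equal(mt$ae_label, sort(unique(recs$vae_name_oae))[1])

  withr::with_seed(31, {
    g <- generate(small_gen(31))
    kb <- compile_kb(g$records, g$seed_terms)
    e <- vaekb:::assoc_entries(kb)
    expect_equal(max_occurrence(kb)$occurrence, max(e$occurrence))
  })

  expect_error(max_occurrence(compile_kb(data.frame(), vaekb_seed_terms())),
               class = "vaekb_empty_kb")
})

test_that("the counting query over the triple view equals the structural analysis", {
  kb <- compile_kb(load_fixture("afluria"), vaekb_seed_terms())
  res <- sparql_lite(kb, fig3_query)
  struct <- count_vae_per_vaccine(kb)
  expect_equal(res$plabel, struct$label)
  expect_equal(res$n, struct$n_vae)
  expect_equal(sub("^obo:", "", res$pclass), struct$id)
})

test_that("subClassOf* uses reflexive-transitive closure", {
  ch <- chain_kb()
  res <- sparql_lite(ch$kb, sprintf(
    "SELECT ?c WHERE { ?c rdfs:subClassOf* <http://purl.obolibrary.org/obo/%s> }",
    ch$C))
  expect_equal(nrow(res), 3L)
  direct <- sparql_lite(ch$kb, sprintf(
    "SELECT ?c WHERE { ?c rdfs:subClassOf obo:%s }", ch$C))
  expect_equal(nrow(direct), 1L)
})

test_that("regex label filters equal a brute-force scan", {
  withr::with_seed(12, {
    g <- generate(small_gen(12))
    kb <- compile_kb(g$records, g$seed_terms)
    res <- sparql_lite(kb,
      'SELECT ?c ?lab WHERE { ?c rdfs:label ?lab . FILTER regex(?lab, "associated") }')
    labs <- vapply(kb$classes, function(c) c$label, character(1))
    expect_setequal(res$lab, unname(labs[grepl("associated", labs)]))
  })
})

test_that("unsupported query syntax raises a parse error with a position", {
  kb <- chain_kb()$kb
  expect_error(sparql_lite(kb, "SELECT ?x WHERE { ?x ?p ?y }"),
               class = "vaekb_query_parse")
  expect_error(sparql_lite(kb, "ASK { ?x rdfs:label ?y }"),
               class = "vaekb_query_parse")
  err <- expect_error(
    sparql_lite(kb, "SELECT ?x WHERE { ?x rdfs:label ?y } HAVING ?x"),
    class = "vaekb_query_parse")
  expect_match(conditionMessage(err), "position")
})

test_that("LIMIT and ORDER BY apply after deterministic tie-breaks", {
  kb <- compile_kb(load_fixture("table2"), vaekb_seed_terms())
  res <- sparql_lite(kb, paste(fig3_query, "LIMIT 3"))
  expect_equal(nrow(res), 3L)
  expect_equal(res$n[1], 20L)
  full <- sparql_lite(kb, fig3_query)
  # ties within equal counts are alphabetical by the remaining selected columns
  ties <- full[full$n == 18L, "plabel"]
  expect_equal(ties, sort(ties))
})
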