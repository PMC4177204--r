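# Shared test helpers: tiny KBs built in code and a random-ontology generator
# for the reasoner property tests.

# chain A -> B -> C (A lowest); returns kb and the three ids
chain_kb <- function() {
  kb <- kb_new()
  C <- term_id("T", 3); B <- term_id("T", 2); A <- term_id("T", 1)
  kb_register_class(kb, ontology_class(C, "C"))
  kb_register_class(kb, ontology_class(B, "B", parents = C))
  kb_register_class(kb, ontology_class(A, "A", parents = B))
  list(kb = kb, A = A, B = B, C = C)
}

# random acyclic KB: named classes with random asserted parents among lower
# indices; a fraction carry a defining expression built from named conjuncts
# and existential restrictions over two roles (fillers always named, so the
# oracle needs no normalization)
random_el_kb <- function(n = 20L, p_def = 0.4) {
  kb <- kb_new()
  ids <- vapply(seq_len(n), function(i) term_id("T", i), character(1))
  roles <- c(PROP_OCCURS_IN, PROP_IS_PRECEDED_BY)
  for (i in seq_len(n)) {
    parents <- if (i > 1L && stats::runif(1) < 0.7)
      sample(ids[seq_len(i - 1L)], min(i - 1L, sample(1:2, 1L)))
    else character()
    expr <- NULL; style <- "subclass"
    if (i > 2L && stats::runif(1) < p_def) {
      named <- sample(ids[seq_len(i - 1L)], sample(1:2, 1L))
      args <- lapply(named, ce_named)
      if (stats::runif(1) < 0.6)
        args <- c(args, list(ce_some(sample(roles, 1L),
                                     ce_named(sample(ids[seq_len(i - 1L)], 1L)))))
      expr <- do.call(ce_and, args)
      style <- if (stats::runif(1) < 0.5) "equivalent" else "subclass"
    }
    kb_register_class(kb, ontology_class(ids[i], sprintf("class %03d", i),
                                         parents = parents,
                                         expression = expr, style = style))
  }
  kb
}

# small generator config for pipeline tests
small_gen <- function(seed, n_vaccines = 6L, ae_vocabulary = 12L,
                      aes_per_vaccine = c(1L, 4L)) {
  generator_config(n_vaccines = n_vaccines, ae_vocabulary = ae_vocabulary,
                   aes_per_vaccine = aes_per_vaccine, seed = seed)
}

fig3_query <- paste(
  'SELECT ?pclass ?plabel (COUNT(?cclass) AS ?n)',
  'WHERE {',
  '  ?cclass rdfs:subClassOf ?pclass .',
  '  ?pclass rdfs:label ?plabel .',
  '  ?cclass rdfs:label ?clabel .',
  '  FILTER regex(?plabel, "adverse event")',
  '  FILTER regex(?clabel, "associated")',
  '}',
  'GROUP BY ?pclass ?plabel',
  'ORDER BY DESC(?n)',
  sep = "\n")
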