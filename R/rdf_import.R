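# Rebuild a KnowledgeBase from its RDF triple view, so Turtle files written
# by this package (or equivalent standard OWL-RDF) can be re-loaded for
# classification and querying.

expr_from_node <- function(node, blank_index) {
  if (node$kind == "iri") {
    if (!startsWith(node$value, "obo:"))
      vaekb_abort("parse", sprintf("unexpected IRI in class expression: %s",
                                   node$value))
    return(ce_named(substring(node$value, 5L)))
  }
  ts <- blank_index[[node$value]]
  if (is.null(ts))
    vaekb_abort("parse", sprintf("dangling blank node %s", node$value))
  po <- function(p) {
    hits <- Filter(function(t) t$p$value == p, ts)
    if (length(hits)) hits[[1L]]$o else NULL
  }
  list_items <- function(head) {
    items <- list()
    cur <- head
    while (!(cur$kind == "iri" && cur$value == "rdf:nil")) {
      lts <- blank_index[[cur$value]]
      first <- Filter(function(t) t$p$value == "rdf:first", lts)[[1L]]$o
      rest <- Filter(function(t) t$p$value == "rdf:rest", lts)[[1L]]$o
      items[[length(items) + 1L]] <- first
      cur <- rest
    }
    items
  }
  type <- po("rdf:type")
  if (!is.null(type) && type$value == "owl:Restriction") {
    prop <- substring(po("owl:onProperty")$value, 5L)
    hv <- po("owl:hasValue")
    if (!is.null(hv)) return(ce_value(prop, as.numeric(hv$value)))
    sv <- po("owl:someValuesFrom")
    if (sv$kind == "blank") {
      svts <- blank_index[[sv$value]]
      svtype <- Filter(function(t) t$p$value == "rdf:type", svts)
      if (length(svtype) && svtype[[1L]]$o$value == "rdfs:Datatype") {
        facets <- list_items(
          Filter(function(t) t$p$value == "owl:withRestrictions", svts)[[1L]]$o)
        lo <- 0; hi <- Inf
        for (f in facets) {
          fts <- blank_index[[f$value]]
          for (t in fts) {
            if (t$p$value == "xsd:minInclusive") lo <- as.numeric(t$o$value)
            if (t$p$value == "xsd:maxInclusive") hi <- as.numeric(t$o$value)
          }
        }
        return(ce_interval(prop, lo, hi))
      }
    }
    return(ce_some(prop, expr_from_node(sv, blank_index)))
  }
  ix <- po("owl:intersectionOf")
  if (!is.null(ix))
    return(do.call(ce_and, lapply(list_items(ix), expr_from_node,
                                  blank_index = blank_index)))
  un <- po("owl:unionOf")
  if (!is.null(un))
    return(do.call(ce_or, lapply(list_items(un), expr_from_node,
                                 blank_index = blank_index)))
  vaekb_abort("parse", sprintf("unrecognized class-expression node %s",
                               node$value))
}

#' Rebuild a knowledge base from a triple view
#'
#' Inverse of [to_triples()]: named `owl:Class` nodes become registered
#' classes (labels, asserted parents, defining expressions), property nodes
#' become property records, and leaf classes whose defining expression has the
#' design-pattern shape are re-materialized as vaccine-AE associations so the
#' full query surface works on a re-loaded KB.
#'
#' @param view A `vae_triples` view, e.g. from [read_turtle()].
#' @return A `vae_kb`.
#' @export
kb_from_triples <- function(view) {
  blank_index <- list()
  named <- list() # curie -> list of triples
  for (t in view$triples) {
    if (t$s$kind == "blank")
      blank_index[[t$s$value]] <- c(blank_index[[t$s$value]], list(t))
    else
      named[[t$s$value]] <- c(named[[t$s$value]], list(t))
  }
  kb <- kb_new()
  pending <- list()
  for (skey in names(named)) {
    if (!startsWith(skey, "obo:")) next
    id <- substring(skey, 5L)
    ts <- named[[skey]]
    types <- vapply(Filter(function(t) t$p$value == "rdf:type", ts),
                    function(t) t$o$value, character(1))
    label <- NULL; parents <- character(); expr <- NULL; style <- "subclass"
    definition <- NULL; def_source <- NULL
    for (t in ts) {
      p <- t$p$value
      if (p == "rdfs:label") label <- t$o$value
      else if (p == "rdfs:subClassOf") {
        if (t$o$kind == "iri") parents <- c(parents, substring(t$o$value, 5L))
        else { expr <- expr_from_node(t$o, blank_index); style <- "subclass" }
      } else if (p == "owl:equivalentClass") {
        expr <- expr_from_node(t$o, blank_index); style <- "equivalent"
      } else if (p == "obo:IAO_0000115") definition <- t$o$value
      else if (p == "obo:IAO_0000119") def_source <- t$o$value
    }
    if ("owl:Class" %in% types) {
      pending[[id]] <- ontology_class(
        id, if (is.null(label)) id else label, parents = parents,
        definition = definition, definition_source = def_source,
        expression = expr, style = style)
    } else if (any(types %in% c("owl:ObjectProperty", "owl:DatatypeProperty"))) {
      kind <- if ("owl:ObjectProperty" %in% types) "object" else "datatype"
      kb_register_property(kb, list(id = id, label = label, kind = kind,
                                    range_hint = if (kind == "datatype")
                                      "decimal" else "class"))
    }
  }
  # topological registration (parents before children)
  while (length(pending)) {
    ready <- names(pending)[vapply(pending, function(c)
      all(c$parents %in% names(kb$classes)), logical(1))]
    if (!length(ready))
      vaekb_abort("dangling_reference",
                  sprintf("unresolvable parents among: %s",
                          paste(names(pending), collapse = ", ")))
    for (id in sort(ready)) {
      kb_register_class(kb, pending[[id]])
      pending[[id]] <- NULL
    }
  }
  rebuild_associations(kb)
  kb
}

# recognize pattern-shaped leaf expressions and re-materialize associations
rebuild_associations <- function(kb) {
  for (id in names(kb$classes)) {
    cls <- kb$classes[[id]]
    e <- cls$expression
    if (is.null(e) || e$type != "and" || length(e$args) != 2L) next
    pop <- NULL
    for (a in e$args)
      if (a$type == "some" && identical(a$property, PROP_OCCURS_IN_POPULATION))
        pop <- a
    if (is.null(pop) || pop$filler$type != "and") next
    parent_labels <- vapply(cls$parents, function(p) kb$classes[[p]]$label,
                            character(1))
    vp <- grepl(" vaccine adverse event$", parent_labels)
    if (sum(vp) != 1L || sum(!vp) != 1L) next
    vaccine_label <- sub(" vaccine adverse event$", "", parent_labels[vp])
    vaccine_id <- kb$label_to_id[vaccine_label]
    if (is.na(vaccine_id)) next
    ae_id <- cls$parents[!vp]
    ae_label <- parent_labels[!vp]
    disj <- Filter(function(a) a$type != "named", pop$filler$args)
    if (length(disj) != 1L) next
    disj <- disj[[1L]]
    group_nodes <- if (disj$type == "or") disj$args else list(disj)
    groups <- lapply(group_nodes, function(g) {
      if (g$type != "and") return(NULL)
      lo <- 0; hi <- Inf; occ <- NA_real_
      for (a in g$args) {
        if (a$type == "interval") { lo <- a$min; hi <- a$max }
        if (a$type == "value") occ <- a$value
      }
      if (is.na(occ)) return(NULL)
      list(min = lo, max = hi,
           category = categorize_age(list(min = lo, max = hi)),
           occurrence = occ)
    })
    if (any(vapply(groups, is.null, logical(1)))) next
    groups <- groups[order(vapply(groups, function(g) g$min, numeric(1)))]
    key <- paste(vaccine_id, ae_id, sep = "|")
    kb$associations[[key]] <- list(
      vaccine = unname(vaccine_id), vaccine_label = vaccine_label,
      ae = ae_id, ae_label = ae_label,
      location = if (grepl("injection-site", ae_label)) "injection-site"
                 else "systemic",
      groups = groups,
      reference = cls$definition_source,
      leaf = id)
  }
  invisible(kb)
}
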