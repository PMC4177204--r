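# Core domain model: term identifiers, the class/property registries that make
# up a knowledge base, and KB-level statistics.
#
# A KnowledgeBase is environment-backed so the registry operations mutate in
# place and can return the identifier they registered, the way mutable-registry
# packages (igraph graphs aside) usually handle ontology stores in R.

TERMID_REGEX <- "^[A-Za-z]+_[0-9]{7}$"

#' Construct a term identifier
#'
#' Term identifiers follow the OBO convention `<PREFIX>_<7 digits>`, e.g.
#' `OVAE_0000001` or `OAE_0000369`. Equality is by the rendered string.
#'
#' @param prefix Uppercase source-ontology prefix (e.g. `"OVAE"`, `"OAE"`).
#' @param serial Positive integer, at most 9999999.
#' @return The rendered identifier, a character scalar.
#' @examples
#' term_id("OVAE", 1)
#' @export
term_id <- function(prefix, serial) {
  serial <- as.integer(serial)
  if (is.na(serial) || serial < 0L || serial > 9999999L)
    vaekb_abort("range", "serial must be an integer in [0, 9999999]")
  sprintf("%s_%07d", prefix, serial)
}

#' Test whether a string is a well-formed term identifier
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_term_id <- function(x) {
  is.character(x) & grepl(TERMID_REGEX, x)
}

#' Source-ontology prefix of a term identifier
#' @param id Term identifier string.
#' @return The prefix, e.g. `"OAE"` for `OAE_0000369`.
#' @export
term_prefix <- function(id) {
  sub("_[0-9]{7}$", "", id)
}

term_serial <- function(id) {
  as.integer(sub("^[A-Za-z]+_", "", id))
}

# ---------------------------------------------------------------------------
# Pattern properties
#
# Five properties participate in the VAE design pattern and are present in
# every KB from construction. All five are minted in the OVAE id space; the
# two age/occurrence properties are datatype properties over xsd:decimal.

PROP_OCCURS_IN_POPULATION <- "OVAE_0000001"
PROP_OCCURS_IN            <- "OVAE_0000002"
PROP_IS_PRECEDED_BY       <- "OVAE_0000003"
PROP_HAS_AGE_IN_YEAR      <- "OVAE_0000004"
PROP_HAS_VAE_OCCURRENCE   <- "OVAE_0000005"

pattern_properties <- function() {
  list(
    list(id = PROP_OCCURS_IN_POPULATION, label = "occurs in population",
         kind = "object", range_hint = "class"),
    list(id = PROP_OCCURS_IN, label = "occurs in",
         kind = "object", range_hint = "class"),
    list(id = PROP_IS_PRECEDED_BY, label = "is preceded by",
         kind = "object", range_hint = "class"),
    list(id = PROP_HAS_AGE_IN_YEAR, label = "has age in year",
         kind = "datatype", range_hint = "decimal"),
    list(id = PROP_HAS_VAE_OCCURRENCE, label = "has VAE occurrence",
         kind = "datatype", range_hint = "decimal")
  )
}

# ---------------------------------------------------------------------------
# KnowledgeBase

#' Create an empty knowledge base
#'
#' The returned object holds the class registry, the property registry (seeded
#' with the five design-pattern properties), the vaccine-AE association list,
#' and, after [classify_kb()], the inferred subsumption closure.
#'
#' @return A `vae_kb` object (environment-backed; operations mutate in place).
#' @export
kb_new <- function() {
  kb <- new.env(parent = emptyenv())
  kb$classes <- list()          # id -> class record
  kb$label_to_id <- character() # names are labels
  kb$children <- list()         # id -> character vector of asserted child ids
  kb$properties <- list()       # id -> property record
  kb$associations <- list()     # keyed "<vaccine>|<ae>"
  kb$inferred <- NULL           # id -> character vector of inferred parents
  class(kb) <- "vae_kb"
  for (p in pattern_properties()) kb_register_property(kb, p)
  kb
}

#' @export
print.vae_kb <- function(x, ...) {
  cat(sprintf(
    "<vae_kb> %d classes, %d properties, %d associations, %s\n",
    length(x$classes), length(x$properties), length(x$associations),
    if (is.null(x$inferred)) "unclassified" else "classified"
  ))
  invisible(x)
}

#' Define an ontology class record
#'
#' @param id Term identifier.
#' @param label Human-readable label, unique within a KB.
#' @param parents Character vector of asserted parent ids (may be empty).
#' @param definition,definition_source Optional annotation text.
#' @param expression Optional defining [class expression][ce_and] (right-hand
#'   side of the class's definitional axiom).
#' @param style `"subclass"` (the class is subsumed by `expression`) or
#'   `"equivalent"` (name defined as equivalent to `expression`).
#' @param source Source-ontology tag; defaults to the id prefix.
#' @return A plain list understood by [kb_register_class()].
#' @export
ontology_class <- function(id, label, parents = character(),
                           definition = NULL, definition_source = NULL,
                           expression = NULL, style = "subclass",
                           source = NULL) {
  if (!is_term_id(id))
    vaekb_abort("parse", sprintf("malformed term id: %s", id))
  if (!style %in% c("subclass", "equivalent"))
    vaekb_abort("parse", "style must be 'subclass' or 'equivalent'")
  list(id = id, label = label, parents = unique(as.character(parents)),
       definition = definition, definition_source = definition_source,
       expression = expression, style = style,
       source = if (is.null(source)) term_prefix(id) else source)
}

kb_register_property <- function(kb, prop) {
  kb$properties[[prop$id]] <- prop
  invisible(prop$id)
}

#' Register a class in a knowledge base
#'
#' Fails if the label or id is already taken, if any asserted parent is not
#' registered, or if the new parent edges would make the asserted subclass
#' graph cyclic.
#'
#' @param kb A `vae_kb`.
#' @param cls A class record from [ontology_class()].
#' @return The registered term id, invisibly.
#' @export
kb_register_class <- function(kb, cls) {
  if (!is.null(kb$classes[[cls$id]]))
    vaekb_abort("duplicate_term", sprintf("id already registered: %s", cls$id))
  if (cls$label %in% names(kb$label_to_id))
    vaekb_abort("duplicate_term",
                sprintf("label already registered: '%s'", cls$label))
  missing <- setdiff(cls$parents, names(kb$classes))
  if (length(missing))
    vaekb_abort("dangling_reference",
                sprintf("unregistered parent(s): %s",
                        paste(missing, collapse = ", ")))
  if (cls$id %in% cls$parents)
    vaekb_abort("cycle", sprintf("%s cannot be its own parent", cls$id))
  kb$classes[[cls$id]] <- cls
  kb$label_to_id[[cls$label]] <- cls$id
  for (p in cls$parents)
    kb$children[[p]] <- c(kb$children[[p]], cls$id)
  kb$inferred <- NULL # registry changed; classification is stale
  invisible(cls$id)
}

#' Add an asserted parent to an existing class
#'
#' @inheritParams kb_register_class
#' @param id,parent Registered term ids.
#' @return `id`, invisibly.
#' @export
kb_add_parent <- function(kb, id, parent) {
  for (t in c(id, parent))
    if (is.null(kb$classes[[t]]))
      vaekb_abort("dangling_reference", sprintf("unregistered class: %s", t))
  if (parent %in% kb$classes[[id]]$parents) return(invisible(id))
  # edge id -> parent creates a cycle iff id is already an ancestor of parent
  if (id == parent || id %in% kb_ancestors(kb, parent))
    vaekb_abort("cycle",
                sprintf("adding %s under %s would create a cycle", id, parent))
  kb$classes[[id]]$parents <- c(kb$classes[[id]]$parents, parent)
  kb$children[[parent]] <- c(kb$children[[parent]], id)
  kb$inferred <- NULL
  invisible(id)
}

#' Attach or replace a class's defining expression
#'
#' @inheritParams kb_add_parent
#' @param expression A class expression (see [ce_and()]).
#' @param style `"subclass"` or `"equivalent"`.
#' @return `id`, invisibly.
#' @export
kb_set_expression <- function(kb, id, expression, style = "subclass") {
  kb_require_class(kb, id)
  if (!style %in% c("subclass", "equivalent"))
    vaekb_abort("parse", "style must be 'subclass' or 'equivalent'")
  kb$classes[[id]]$expression <- expression
  kb$classes[[id]]$style <- style
  kb$inferred <- NULL
  invisible(id)
}

#' Look up a class by id or by label
#' @param kb A `vae_kb`.
#' @param what A term id or an exact label.
#' @return The class record, or `NULL` if absent.
#' @export
kb_class <- function(kb, what) {
  if (!is.null(kb$classes[[what]])) return(kb$classes[[what]])
  id <- kb$label_to_id[what]
  if (!is.na(id)) kb$classes[[id]] else NULL
}

kb_class_ids <- function(kb) names(kb$classes)

kb_require_class <- function(kb, id) {
  if (is.null(kb$classes[[id]]))
    vaekb_abort("dangling_reference", sprintf("unregistered class: %s", id))
  invisible(id)
}

# ancestors via asserted parent links (id itself excluded)
kb_ancestors <- function(kb, id) {
  seen <- character()
  stack <- kb$classes[[id]]$parents
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    stack <- c(stack, kb$classes[[x]]$parents)
  }
  seen
}

#' Descendants of a term
#'
#' @param kb A `vae_kb`.
#' @param id Registered term id.
#' @param inferred If `TRUE`, use the inferred hierarchy (requires
#'   [classify_kb()] to have run); otherwise use asserted parents only.
#' @return Character vector of descendant ids, `id` itself excluded.
#' @export
kb_descendants <- function(kb, id, inferred = FALSE) {
  kb_require_class(kb, id)
  if (inferred) {
    if (is.null(kb$inferred))
      vaekb_abort("classification_not_run",
                  "classify_kb() has not been run on this KB")
    ids <- names(kb$classes)
    return(ids[vapply(ids, function(x) id %in% kb$inferred[[x]], logical(1)) &
                 ids != id])
  }
  seen <- character()
  stack <- kb$children[[id]]
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    stack <- c(stack, kb$children[[x]])
  }
  sort(seen)
}

#' Per-source term statistics
#'
#' Tallies classes and properties by source-ontology tag, mirroring the usual
#' "summary of ontology terms" table, with a totals row whose entries are the
#' column sums.
#'
#' @param kb A `vae_kb`.
#' @return A data frame with columns `source`, `n_classes`,
#'   `n_object_properties`, `n_datatype_properties`, `total`; last row is
#'   `Total`.
#' @export
term_statistics <- function(kb) {
  src_cls <- vapply(kb$classes, function(c) c$source, character(1))
  src_obj <- vapply(Filter(function(p) p$kind == "object", kb$properties),
                    function(p) term_prefix(p$id), character(1))
  src_dat <- vapply(Filter(function(p) p$kind == "datatype", kb$properties),
                    function(p) term_prefix(p$id), character(1))
  sources <- sort(unique(c(src_cls, src_obj, src_dat)))
  tab <- data.frame(
    source = sources,
    n_classes = vapply(sources, function(s) sum(src_cls == s), integer(1)),
    n_object_properties =
      vapply(sources, function(s) sum(src_obj == s), integer(1)),
    n_datatype_properties =
      vapply(sources, function(s) sum(src_dat == s), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$total <- tab$n_classes + tab$n_object_properties + tab$n_datatype_properties
  totals <- data.frame(source = "Total",
                       n_classes = sum(tab$n_classes),
                       n_object_properties = sum(tab$n_object_properties),
                       n_datatype_properties = sum(tab$n_datatype_properties),
                       total = sum(tab$total),
                       stringsAsFactors = FALSE)
  rbind(tab, totals)
}

# ---------------------------------------------------------------------------
# Class expressions
#
# Expressions are nested plain lists tagged by `type`:
#   named     - reference to a registered class
#   some      - existential restriction (object property, class filler)
#   interval  - datatype restriction to a closed decimal interval (max may be Inf)
#   value     - datatype value restriction (a single decimal)
#   and / or  - n-ary connectives; `or` is only legal as (part of) the filler
#               of an 'occurs in population' restriction.

#' Class-expression constructors
#'
#' Build the nested expression lists used as defining expressions of ontology
#' classes. `ce_or()` is only valid inside the filler of an
#' `'occurs in population'` restriction (the design pattern's OR-clause over
#' age groups); this is enforced at compile/normalization time.
#'
#' @param ... Sub-expressions (for `ce_and`/`ce_or`).
#' @param id Term id (for `ce_named`).
#' @param property Property id (for the restriction forms).
#' @param filler Filler expression (for `ce_some`).
#' @param min,max Closed interval bounds in decimal years; `max = Inf` for an
#'   open-ended upper bound (for `ce_interval`).
#' @param value Decimal value (for `ce_value`).
#' @return An expression node (plain tagged list).
#' @name class_expression
NULL

#' @rdname class_expression
#' @export
ce_named <- function(id) list(type = "named", id = id)

#' @rdname class_expression
#' @export
ce_some <- function(property, filler)
  list(type = "some", property = property, filler = filler)

#' @rdname class_expression
#' @export
ce_interval <- function(property, min, max)
  list(type = "interval", property = property, min = min, max = max)

#' @rdname class_expression
#' @export
ce_value <- function(property, value)
  list(type = "value", property = property, value = value)

#' @rdname class_expression
#' @export
ce_and <- function(...) list(type = "and", args = list(...))

#' @rdname class_expression
#' @export
ce_or <- function(...) list(type = "or", args = list(...))

# canonical single-line rendering; used for opaque-atom keys and debugging
ce_render <- function(e) {
  switch(e$type,
    named = e$id,
    some = sprintf("some(%s,%s)", e$property, ce_render(e$filler)),
    interval = sprintf("interval(%s,%s,%s)", e$property,
                       format_decimal(e$min), format_decimal(e$max)),
    value = sprintf("value(%s,%s)", e$property, format_decimal(e$value)),
    and = sprintf("and(%s)",
                  paste(sort(vapply(e$args, ce_render, character(1))),
                        collapse = ",")),
    or = sprintf("or(%s)",
                 paste(sort(vapply(e$args, ce_render, character(1))),
                       collapse = ",")),
    vaekb_abort("parse", sprintf("unknown expression type: %s", e$type))
  )
}

# fixed-point decimal rendering (no scientific notation), used everywhere a
# decimal must serialize deterministically
format_decimal <- function(x) {
  vapply(x, function(xi) {
    if (is.infinite(xi)) "Inf"
    else format(xi, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
}
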