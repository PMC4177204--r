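# Compilation of vaccine-AE associations into ontology classes and axioms.
#
# Every compiled leaf follows one fixed design pattern: the vaccine-specific
# adverse event is preceded by a vaccination with that vaccine and occurs in a
# human vaccinee population restricted by age (in years) and carrying the
# reported occurrence rate. Age groups are combined with an OR-clause inside
# the 'occurs in population' filler.

#' Create an id minter for OVAE-space identifiers
#'
#' Ids are `OVAE_` plus seven auto-incrementing digits. Minting skips over any
#' reserved ids (e.g. the pattern properties or seed terms already in the
#' OVAE id space).
#'
#' @param reserved Character vector of ids that must never be minted.
#' @param start First serial to try (default 1).
#' @return An environment-backed minter for [mint_ovae_id()].
#' @export
id_minter <- function(reserved = character(), start = 1L) {
  m <- new.env(parent = emptyenv())
  m$next_serial <- as.integer(start)
  m$reserved <- unique(reserved)
  class(m) <- "vae_minter"
  m
}

#' Mint the next OVAE id
#' @param minter A minter from [id_minter()].
#' @return A fresh `OVAE_xxxxxxx` id; the minter advances past it and past any
#'   reserved ids.
#' @export
mint_ovae_id <- function(minter) {
  repeat {
    if (minter$next_serial > 9999999L)
      vaekb_abort("capacity", "OVAE serial space exhausted")
    id <- term_id("OVAE", minter$next_serial)
    minter$next_serial <- minter$next_serial + 1L
    if (!id %in% minter$reserved) {
      minter$reserved <- c(minter$reserved, id)
      return(id)
    }
  }
}

# root labels auto-created during compilation when the seed does not supply them
ROOT_VAE <- "vaccine adverse event"
ROOT_HVP <- "human vaccinee population"
ROOT_VACCINATION <- "vaccination"
ROOT_AE <- "adverse event"
ROOT_VACCINE <- "vaccine"

ensure_root <- function(kb, minter, label, parent_label = NULL) {
  cls <- kb_class(kb, label)
  if (!is.null(cls)) return(cls$id)
  parents <- character()
  if (!is.null(parent_label)) {
    p <- kb_class(kb, parent_label)
    if (!is.null(p)) parents <- p$id
  }
  kb_register_class(kb, ontology_class(mint_ovae_id(minter), label,
                                       parents = parents, source = "OVAE"))
  kb_class(kb, label)$id
}

#' Per-vaccine adverse-event parent class
#'
#' Returns (creating on first call) the class labelled
#' `"<vaccine label> vaccine adverse event"`, asserted under the
#' `'vaccine adverse event'` root. Idempotent.
#'
#' @param kb A `vae_kb`.
#' @param vaccine_id Registered vaccine term id.
#' @param minter Minter for fresh OVAE ids.
#' @return The parent class term id.
#' @export
vaccine_ae_parent <- function(kb, vaccine_id, minter) {
  kb_require_class(kb, vaccine_id)
  label <- paste(kb$classes[[vaccine_id]]$label, "vaccine adverse event")
  existing <- kb_class(kb, label)
  if (!is.null(existing)) return(existing$id)
  root <- ensure_root(kb, minter, ROOT_VAE, ROOT_AE)
  id <- mint_ovae_id(minter)
  kb_register_class(kb, ontology_class(id, label, parents = root,
                                       source = "OVAE"))
  id
}

# the vaccination-event intermediary: 'vaccination with <vaccine>' under the
# 'vaccination' root; fills the 'is preceded by' restriction
vaccination_event_class <- function(kb, vaccine_id, minter) {
  kb_require_class(kb, vaccine_id)
  label <- paste("vaccination with", kb$classes[[vaccine_id]]$label)
  existing <- kb_class(kb, label)
  if (!is.null(existing)) return(existing$id)
  root <- ensure_root(kb, minter, ROOT_VACCINATION)
  id <- mint_ovae_id(minter)
  kb_register_class(kb, ontology_class(id, label, parents = root,
                                       source = "OVAE"))
  id
}

# strip a trailing " AE" / " adverse event" before composing the leaf label
ae_label_stem <- function(label) {
  sub(" (AE|adverse event)$", "", label)
}

#' Compile one association into its leaf VAE class
#'
#' Creates the class labelled
#' `"<vaccine>-associated <AE stem> AE"` with two asserted parents (the OAE
#' adverse-event term and the vaccine's `'... vaccine adverse event'` parent)
#' and the pattern axiom as a SubClassOf defining expression:
#' `'is preceded by' some (vaccination with V)` and
#' `'occurs in population' some ('human vaccinee population' and D)` where `D`
#' is the OR over age groups of
#' `('has age in year' in [min,max]) and ('has VAE occurrence' value p)`.
#' With a single age group the OR node degenerates away. Idempotent.
#'
#' @param kb A `vae_kb`.
#' @param assoc One association from [records_to_associations()].
#' @param minter Minter for fresh OVAE ids.
#' @return The leaf class term id.
#' @export
build_vae_class <- function(kb, assoc, minter) {
  kb_require_class(kb, assoc$vaccine)
  kb_require_class(kb, assoc$ae)
  vlabel <- kb$classes[[assoc$vaccine]]$label
  alabel <- kb$classes[[assoc$ae]]$label
  leaf_label <- sprintf("%s-associated %s AE", vlabel, ae_label_stem(alabel))
  existing <- kb_class(kb, leaf_label)
  if (!is.null(existing)) return(existing$id)

  parent_id <- vaccine_ae_parent(kb, assoc$vaccine, minter)
  vacc_event <- vaccination_event_class(kb, assoc$vaccine, minter)
  hvp <- ensure_root(kb, minter, ROOT_HVP)

  group_expr <- function(g) {
    ce_and(ce_interval(PROP_HAS_AGE_IN_YEAR, g$min, g$max),
           ce_value(PROP_HAS_VAE_OCCURRENCE, g$occurrence))
  }
  exprs <- lapply(assoc$groups, group_expr)
  pop_restriction <- if (length(exprs) == 1L) exprs[[1L]]
                     else do.call(ce_or, exprs)
  expr <- ce_and(
    ce_some(PROP_IS_PRECEDED_BY, ce_named(vacc_event)),
    ce_some(PROP_OCCURS_IN_POPULATION,
            ce_and(ce_named(hvp), pop_restriction))
  )
  id <- mint_ovae_id(minter)
  kb_register_class(kb, ontology_class(
    id, leaf_label,
    parents = c(assoc$ae, parent_id),
    definition_source = assoc$reference,
    expression = expr, style = "subclass", source = "OVAE"
  ))
  key <- paste(assoc$vaccine, assoc$ae, sep = "|")
  if (!is.null(kb$associations[[key]]))
    vaekb_abort("duplicate_term",
                sprintf("association already compiled: %s", key))
  assoc$leaf <- id
  kb$associations[[key]] <- assoc
  id
}

#' Read a seed term table
#'
#' Seed tables carry mini class hierarchies (e.g. a mini-OAE) as CSV with
#' header `id,label,parent_ids,source`; `parent_ids` is pipe-separated and may
#' be empty for roots; `source` defaults to the id prefix.
#'
#' @param path CSV path.
#' @return Data frame with those four character columns.
#' @export
read_seed_terms <- function(path) {
  if (!file.exists(path))
    vaekb_abort("schema", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  need <- c("id", "label", "parent_ids", "source")
  if (!all(need %in% names(df)))
    vaekb_abort("schema",
                sprintf("seed table must have columns %s",
                        paste(need, collapse = ", ")))
  df[need]
}

# register seed rows, tolerating arbitrary row order (children before parents)
register_seed_terms <- function(kb, seed) {
  pending <- seq_len(nrow(seed))
  repeat {
    progressed <- FALSE
    still <- integer()
    for (i in pending) {
      parents <- strsplit(seed$parent_ids[i], "|", fixed = TRUE)[[1]]
      parents <- parents[nzchar(parents)]
      if (all(parents %in% names(kb$classes))) {
        src <- seed$source[i]
        kb_register_class(kb, ontology_class(
          seed$id[i], seed$label[i], parents = parents,
          source = if (nzchar(src)) src else NULL))
        progressed <- TRUE
      } else {
        still <- c(still, i)
      }
    }
    pending <- still
    if (!length(pending)) break
    if (!progressed)
      vaekb_abort("dangling_reference",
                  sprintf("seed rows with unresolvable parents: %s",
                          paste(seed$id[pending], collapse = ", ")))
  }
  invisible(kb)
}

#' Compile template records into a knowledge base
#'
#' Deterministic end-to-end compilation: seed terms are registered, the
#' records are merged into associations, and associations are compiled in
#' (vaccine label, AE label) order so that minted ids — and hence the Turtle
#' serialization — are reproducible byte for byte.
#'
#' @param records Template record data frame ([read_template()]).
#' @param seed_terms Seed term table ([read_seed_terms()]); should contain the
#'   adverse-event terms referenced by `oae_id` and usually an
#'   `'adverse event'` and a `'vaccine'` root. Vaccines missing from the seed
#'   are registered from the records themselves.
#' @return A compiled `vae_kb`.
#' @export
compile_kb <- function(records, seed_terms = NULL) {
  kb <- kb_new()
  if (!is.null(seed_terms) && nrow(seed_terms))
    register_seed_terms(kb, seed_terms)
  minter <- id_minter(reserved = grep("^OVAE_", names(kb$classes), value = TRUE))
  for (p in pattern_properties()) minter$reserved <- c(minter$reserved, p$id)

  ensure_root(kb, minter, ROOT_VAE, ROOT_AE)
  ensure_root(kb, minter, ROOT_HVP)

  assocs <- records_to_associations(records)
  if (length(assocs)) {
    labs <- vapply(assocs, function(a)
      paste(a$vaccine_label, a$ae_label, sep = "\r"), character(1))
    assocs <- assocs[order(labs, method = "radix")]
    for (a in assocs) {
      if (is.null(kb$classes[[a$vaccine]])) {
        root <- kb_class(kb, ROOT_VACCINE)
        kb_register_class(kb, ontology_class(
          a$vaccine, a$vaccine_label,
          parents = if (is.null(root)) character() else root$id))
      }
      if (is.null(kb$classes[[a$ae]]))
        vaekb_abort("dangling_reference",
                    sprintf("AE term %s (%s) not in seed table", a$ae, a$ae_label))
      build_vae_class(kb, a, minter)
    }
  }
  kb
}
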